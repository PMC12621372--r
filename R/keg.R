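#' Write and read keg archives
#'
#' A *keg* is the hand-off between the GPU-friendly seed/filter half of the
#' pipeline and the CPU-only batched gapped-extension half: a
#' gzip-compressed tar archive holding `partitions/` (one segment file per
#' partition), `commands.txt` (one rendered extension command per
#' partition, in plan order) and `manifest.tsv` (the plan metadata). A keg
#' can be produced on one machine and executed on another with
#' [run_batch()].
#'
#' @param partition_paths Segment files to bundle, in plan order.
#' @param command_template Command text containing a `{segments}`
#'   placeholder (replaced by the in-archive partition path) and optionally
#'   `{output}` (replaced at execution time by the per-command output
#'   path).
#' @param out_path Archive path to create (conventionally `.keg.tar.gz`).
#' @param manifest Optional data frame written as `manifest.tsv`; defaults
#'   to a minimal name/size table.
#' @return `out_path`, invisibly.
#' @export
write_keg <- function(partition_paths, command_template, out_path,
                      manifest = NULL) {
  if (!grepl("{segments}", command_template, fixed = TRUE))
    stop("command_template must contain a {segments} placeholder")
  missing <- partition_paths[!file.exists(partition_paths)]
  if (length(missing))
    stop("partition file(s) not found: ", paste(missing, collapse = ", "))
  names_in <- basename(partition_paths)
  if (anyDuplicated(names_in))
    stop("partition file basenames must be unique within a keg")

  stage <- tempfile("keg_stage_")
  dir.create(file.path(stage, "partitions"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE))
  file.copy(partition_paths, file.path(stage, "partitions", names_in))
  commands <- vapply(names_in, function(nm)
    gsub("{segments}", file.path("partitions", nm), command_template,
         fixed = TRUE), "")
  writeLines(unname(commands), file.path(stage, "commands.txt"))
  if (is.null(manifest)) {
    manifest <- data.frame(file = file.path("partitions", names_in),
                           bytes = file.size(partition_paths))
  }
  write.table(manifest, file.path(stage, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  out_path <- normalizePath(out_path, mustWork = FALSE)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  tar(out_path, files = c("partitions", "commands.txt", "manifest.tsv"),
      compression = "gzip", tar = "internal")
  invisible(out_path)
}

#' @rdname write_keg
#' @param path A keg archive.
#' @return `read_keg()` returns a `keg` object: `dir` (extraction
#'   directory), `partitions` (named vector of extracted paths, in command
#'   order), `commands` and `manifest`.
#' @export
read_keg <- function(path) {
  if (!file.exists(path)) stop("keg archive not found: ", path)
  exdir <- tempfile("keg_")
  dir.create(exdir)
  untar(path, exdir = exdir, tar = "internal")
  cmd_path <- file.path(exdir, "commands.txt")
  if (!file.exists(cmd_path))
    stop("invalid keg: missing commands.txt")
  commands <- readLines(cmd_path, warn = FALSE)
  commands <- commands[commands != ""]
  refs <- regmatches(commands, regexpr("partitions/[^ '\"]+", commands))
  if (length(refs) != length(commands))
    stop("invalid keg: command without a partitions/ reference")
  ok <- file.exists(file.path(exdir, refs))
  if (!all(ok))
    stop("invalid keg: command line ", which(!ok)[1],
         " references missing entry '", refs[!ok][1], "'")
  manifest <- if (file.exists(file.path(exdir, "manifest.tsv")))
    read.delim(file.path(exdir, "manifest.tsv"), stringsAsFactors = FALSE)
  else NULL
  structure(list(dir = exdir,
                 partitions = structure(file.path(exdir, refs), names = refs),
                 commands = commands, manifest = manifest),
            class = "keg")
}

#' @export
print.keg <- function(x, ...) {
  cat(sprintf("<keg> %d partitions, %d commands\n",
              length(x$partitions), length(x$commands)))
  invisible(x)
}

#' Execute a keg's command batch
#'
#' Runs every command of a keg on a worker pool. Each command writes to its
#' own per-command file; once all commands finish the per-command outputs
#' are concatenated *in command order* (with MAF header deduplication), so
#' the final output is byte-identical for any worker count and any
#' completion order. Intermediate outputs go to disk rather than through
#' pipes, so slow consumers can never block producers.
#'
#' @param keg A `keg` object from [read_keg()].
#' @param executor Either `shell_executor()` — run each command line with
#'   [system()] — or any function `f(command, segments_path, output_path)`
#'   returning a 0/nonzero exit status, e.g. [toy_executor()].
#' @param workers Number of parallel workers (>= 1).
#' @param out_dir Directory for per-command outputs and the concatenated
#'   result (default: a fresh temporary directory).
#' @return A `batch_result` list: `status` (integer per command),
#'   `output_paths`, and `concatenated` (path of the merged MAF). If any
#'   command fails the error names the failing command indices; partial
#'   outputs are kept in `out_dir` for inspection.
#' @export
run_batch <- function(keg, executor, workers = 1L, out_dir = tempfile("batch_")) {
  stopifnot(inherits(keg, "keg"), workers >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(keg$commands)
  out_paths <- file.path(out_dir, sprintf("cmd%05d.out", seq_len(n)))
  concat <- file.path(out_dir, "batch.maf")
  if (n == 0L) {
    file.create(concat)
    return(structure(list(status = integer(), output_paths = character(),
                          concatenated = concat, dir = out_dir),
                     class = "batch_result"))
  }
  run_one <- function(i) {
    cmd <- gsub("{output}", out_paths[i], keg$commands[i], fixed = TRUE)
    st <- tryCatch(executor(cmd, keg$partitions[[i]], out_paths[i]),
                   error = function(e) {
                     message("command ", i, " failed: ", conditionMessage(e))
                     1L
                   })
    as.integer(st)
  }
  status <- if (workers == 1L) {
    vapply(seq_len(n), run_one, integer(1))
  } else {
    unlist(parallel::mclapply(seq_len(n), run_one, mc.cores = workers))
  }
  failed <- which(status != 0L)
  if (length(failed))
    stop("batch failed for command(s): ", paste(failed, collapse = ", "),
         " (partial outputs kept in ", out_dir, ")")
  maf_concat(out_paths, concat)
  structure(list(status = status, output_paths = out_paths,
                 concatenated = concat, dir = out_dir),
            class = "batch_result")
}

#' Built-in executors for [run_batch()]
#'
#' `toy_executor()` closes over the target/query sequences and a score
#' model and processes each partition with the package's own gapped
#' extender: it reads the segment file, honours a `#window t0 t1 q0 q1`
#' comment (written by the pipeline to bound extension to the originating
#' chunk), runs [gapped_extend()], and writes MAF. `shell_executor()` runs
#' the rendered command line through the shell, sending stdout to the
#' per-command output file; use it to drive an external gapped-extension
#' binary.
#'
#' @param target,query Sequences (character or codes).
#' @param model A [score_model()].
#' @return A function suitable as the `executor` argument of [run_batch()].
#' @export
toy_executor <- function(target, query, model = score_model()) {
  tc <- if (is.character(target)) encode_dna(target) else target
  qc <- if (is.character(query)) encode_dna(query) else query
  function(command, segments_path, output_path) {
    recs <- read_segments(segments_path)
    win <- read_window_comment(segments_path)
    alns <- gapped_extend(tc, qc, recs, model,
                          t_window = win$t, q_window = win$q)
    write_maf(alns, tc, qc, output_path)
    0L
  }
}

#' @rdname toy_executor
#' @param nice Optional niceness increment applied to each command (Unix
#'   `nice`), so heavy extension batches do not starve interactive work;
#'   default none.
#' @export
shell_executor <- function(nice = NULL) {
  function(command, segments_path, output_path) {
    if (!is.null(nice)) command <- sprintf("nice -n %d %s", nice, command)
    if (!grepl(output_path, command, fixed = TRUE))
      command <- paste(command, ">", shQuote(output_path))
    system(command)
  }
}

read_window_comment <- function(path) {
  head <- readLines(path, n = 20L, warn = FALSE)
  w <- grep("^#window\\s", head, value = TRUE)
  if (length(w) == 0L) return(list(t = NULL, q = NULL))
  v <- as.integer(strsplit(trimws(sub("^#window", "", w[1])), "\\s+")[[1]])
  list(t = v[1:2], q = v[3:4])
}
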