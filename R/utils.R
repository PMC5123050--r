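# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("'", name, "' must be >= 0", call. = FALSE)
  invisible(x)
}

# Write a text file atomically: write to a sibling temp path, then rename.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }, path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = ".", stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(df)))
    stop("file ", path, " lacks required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  df
}

write_json <- function(x, path) {
  write_atomic(function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != floor(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  as.integer(seed)
}
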