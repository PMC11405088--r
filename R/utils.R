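#' @keywords internal
"_PACKAGE"

# Logging: a single stream to stderr, gated by a package option.
# Levels: debug < info < warn. Set via options(binderclust.log_level = "warn")
# or the log_level field of pipeline_config().
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

bc_log <- function(level, fmt, ...) {
  thr <- getOption("binderclust.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Set the package logging level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn")) {
  level <- match.arg(level)
  old <- getOption("binderclust.log_level", "info")
  options(binderclust.log_level = level)
  invisible(old)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single value in [0, 1], got %s", name,
          paste(format(x), collapse = ","))
  }
  invisible(x)
}

# Convert a sorted integer vector of 0-based residue indices into a k x 2
# matrix of half-open [start, end) intervals over maximal runs.
indices_to_intervals <- function(idx) {
  if (length(idx) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  idx <- sort(unique(as.integer(idx)))
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))] + 1L
  matrix(c(starts, ends), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

intervals_to_indices <- function(iv) {
  if (nrow(iv) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(k) seq(iv[k, 1L], iv[k, 2L] - 1L)),
         use.names = FALSE)
}

# Deterministic CSV writer: LF line endings, no quoting surprises, numbers
# pre-formatted by the caller where byte stability matters.
write_csv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(path)
}

fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}
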