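#' The five-stage sleep label space
#'
#' The ordered label space used throughout the package: Wake, REM, and the
#' three non-REM stages. Stage codes are 0-based indices into this vector,
#' so W = 0, REM = 1, N1 = 2, N2 = 3, N3 = 4. Every matrix with a stage
#' dimension (transition matrices, posterior matrices, confusion matrices)
#' uses this row/column order.
#'
#' @return Character vector `c("W", "REM", "N1", "N2", "N3")`.
#' @export
#' @examples
#' stage_labels()
stage_labels <- function() c("W", "REM", "N1", "N2", "N3")

#' @rdname stage_labels
#' @export
n_stages <- function() 5L

#' Convert between stage labels and 0-based stage codes
#'
#' @param x For `stage_code`, a character vector of labels among
#'   `stage_labels()`; for `stage_label`, an integer vector of codes in 0..4.
#' @return Integer codes in 0..4, or character labels.
#' @export
stage_code <- function(x) {
  idx <- match(x, stage_labels())
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' @rdname stage_code
#' @export
stage_label <- function(x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 0L) || any(x > 4L)) {
    stop("stage codes must be integers in 0..4", call. = FALSE)
  }
  stage_labels()[x + 1L]
}

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels for one study
#' night, scored on a fixed epoch grid (30 s by convention).
#'
#' @param stages Integer vector of 0-based stage codes (0..4), or a character
#'   vector of labels among `stage_labels()`.
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @return An object of class `"hypnogram"`: an integer vector of stage codes
#'   with attribute `epoch_seconds`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2", "N3"))
#' print(h)
hypnogram <- function(stages, epoch_seconds = 30) {
  if (is.character(stages)) stages <- stage_code(stages)
  stages <- as.integer(stages)
  if (length(stages) > 0 && (any(is.na(stages)) || any(stages < 0L) || any(stages > 4L))) {
    stop("stage codes must lie in 0..4", call. = FALSE)
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1 || epoch_seconds <= 0) {
    stop("epoch_seconds must be a positive scalar", call. = FALSE)
  }
  structure(stages, epoch_seconds = as.numeric(epoch_seconds), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x), " epochs of ", attr(x, "epoch_seconds"), " s\n", sep = "")
  tab <- table(factor(stage_label(as.integer(x)), levels = stage_labels()))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) {
  hypnogram(unclass(x)[i], epoch_seconds = attr(x, "epoch_seconds"))
}

n_epochs <- function(h) length(h)

check_same_length <- function(..., what = "inputs") {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1) {
    stop(what, " must have equal lengths (got ", paste(lens, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(lens[1])
}

#' Read and write hypnogram CSV files
#'
#' The interchange schema is `epoch_index` (0-based) and `stage_label`
#' (W/REM/N1/N2/N3). Stage labels are always serialized as strings, never as
#' bare codes.
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @param extra Optional named list of constant columns appended to the CSV
#'   (e.g. a `method` tag for reviewed hypnograms).
#' @return `read_hypnogram_csv` returns a [hypnogram()];
#'   `write_hypnogram_csv` returns `path` invisibly.
#' @export
write_hypnogram_csv <- function(h, path, extra = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(h) - 1L,
                   stage_label = stage_label(as.integer(h)),
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param epoch_seconds Epoch duration to attach on read.
#' @export
read_hypnogram_csv <- function(path, epoch_seconds = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "stage_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("hypnogram CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  hypnogram(df$stage_label, epoch_seconds = epoch_seconds)
}
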