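## Internal helpers shared across modules.

# Labels accepted (case-insensitively) as the control / wild-type sentinel.
.CONTROL_ALIASES <- c("control", "ctrl")

#' Canonical control / wild-type sentinel label
#'
#' Per-cell KO labels equal to this value (or an accepted alias,
#' case-insensitively) mark unperturbed control cells.
#' @export
CONTROL <- "control"

.isControlLabel <- function(x) tolower(trimws(as.character(x))) %in% .CONTROL_ALIASES

.normalizeKoLabels <- function(ko) {
  ko <- as.character(ko)
  ko[.isControlLabel(ko)] <- CONTROL
  ko
}

# Overflow-safe logistic.
.logistic <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# Deterministic child seeds derived from a master seed (kept < 2^31).
.childSeeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(2147483L, n) * 1000L + sample.int(999L, n, replace = TRUE)
}

# Detect field separator of a delimited text file from its header line.
.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Raw time labels in time-index order.
.timeLabels <- function(dataset) {
  tm <- S4Vectors::metadata(dataset)$time_map
  if (!is.null(tm)) return(as.character(tm$time_label))
  ti <- timeIndex(dataset)
  tl <- timeLabel(dataset)
  as.character(tl[match(sort(unique(ti)), ti)])
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
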