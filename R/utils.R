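# Internal helpers shared across the package.

## The 20 standard amino acids, alphabetical one-letter codes. All PWMs and
## intensity matrices use this row order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_CHAR <- "-"

#' @importFrom methods is new slot validObject
#' @importFrom stats p.adjust pbinom phyper rbinom rgamma rnorm setNames
#' @importFrom utils read.delim write.table
NULL

## Split windows into an n x width character matrix.
windowMatrix <- function(windows, width = NULL) {
  if (length(windows) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = if (is.null(width)) 0L else width))
  }
  w <- nchar(windows[1L])
  if (!is.null(width) && w != width) {
    stop("windows have width ", w, ", expected ", width)
  }
  if (any(nchar(windows) != w)) {
    stop("windows do not share a common width")
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = w, byrow = TRUE)
}

## Position labels for a window of odd width: -h..-1, 1..h (center excluded).
flankPositions <- function(width) {
  h <- (width - 1L) %/% 2L
  c(seq.int(-h, -1L), seq.int(1L, h))
}

## Column index in a width-w window for a relative position (center = 0).
posToCol <- function(pos, width) {
  as.integer(pos + (width + 1L) %/% 2L)
}

## Format numbers with 6 significant digits for deterministic table output.
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6L), digits = 6L, format = "g"))
}

## Derive independent per-stage seeds from one master seed, kept below 2^31.
stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, classify = 23L, modules = 37L,
               enrich = 53L, match = 71L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% 2147483587)
}

## Write a data.frame as TSV with fixed column order and no quoting.
writeTSV <- function(df, path, float_cols = NULL) {
  out <- df
  for (cn in intersect(float_cols, names(out))) {
    out[[cn]] <- fmtNum(out[[cn]])
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
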