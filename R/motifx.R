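# Phospho-motif extraction: an iterative greedy binomial-enrichment
# algorithm in the style of motif-x. Within each central residue (s* or t*),
# the most significantly enriched (position, residue) pair is fixed, windows
# not matching it are removed from both foreground and background, and the
# search repeats on the reduced sets until no pair reaches the significance
# and occurrence thresholds; the matched windows form a module and the
# search restarts on the remaining foreground.

#' Motif extraction parameters
#'
#' Defaults follow the standard parameterization for phospho-proteome motif
#' extraction: width 13 (positions -6..+6), central residue s* or t*, minimum
#' 10 motif occurrences, binomial significance 1e-6.
#'
#' @param width odd window width >= 3 (default 13).
#' @param centralResidues subset of \code{c("S","T","Y")} (default S and T).
#' @param minOccurrences minimum module size (default 10).
#' @param significance per-fixation binomial p-value threshold (default
#'   1e-6).
#' @return A validated parameter list.
#' @export
motifParams <- function(width = 13L, centralResidues = c("S", "T"),
                        minOccurrences = 10L, significance = 1e-6) {
  width <- as.integer(width)
  if (width < 3L || width %% 2L == 0L) stop("width must be odd and >= 3")
  if (!all(centralResidues %in% c("S", "T", "Y"))) {
    stop("centralResidues must be a subset of S, T, Y")
  }
  if (minOccurrences < 1L) stop("minOccurrences must be >= 1")
  if (significance <= 0 || significance >= 1) {
    stop("significance must be in (0, 1)")
  }
  list(width = width, centralResidues = centralResidues,
       minOccurrences = as.integer(minOccurrences),
       significance = significance)
}

#' Extract the sequence window around a phospho-site
#'
#' @param proteome named character vector of protein sequences.
#' @param proteinId protein identifier.
#' @param sitePos 1-based position of the phospho-acceptor in the protein.
#' @param width odd window width (default 13).
#' @return Character window of length \code{width}, centered on the site and
#'   padded with \code{'-'} beyond the protein termini.
#' @export
extractWindow <- function(proteome, proteinId, sitePos, width = 13L) {
  if (!proteinId %in% names(proteome)) stop("unknown protein: ", proteinId)
  seq <- proteome[[proteinId]]
  L <- nchar(seq)
  if (sitePos < 1L || sitePos > L) {
    stop("site position ", sitePos, " out of range for ", proteinId,
         " (length ", L, ")")
  }
  h <- (width - 1L) %/% 2L
  lo <- sitePos - h
  hi <- sitePos + h
  core <- substr(seq, max(1L, lo), min(L, hi))
  paste0(strrep(PAD_CHAR, max(0L, 1L - lo)), core,
         strrep(PAD_CHAR, max(0L, hi - L)))
}

#' All proteome windows centered on given residues
#'
#' The motif background: one window per occurrence of each central residue
#' anywhere in the proteome.
#'
#' @param proteome named character vector of protein sequences.
#' @param centralResidues residues to center on (e.g. \code{c("S","T")}).
#' @param width odd window width (default 13).
#' @return Character vector of windows.
#' @export
backgroundWindows <- function(proteome, centralResidues = c("S", "T"),
                              width = 13L) {
  if (length(proteome) == 0L) stop("proteome is empty")
  pat <- paste0("[", paste(centralResidues, collapse = ""), "]")
  out <- vector("list", length(proteome))
  for (i in seq_along(proteome)) {
    hits <- gregexpr(pat, proteome[[i]])[[1L]]
    if (hits[1L] == -1L) next
    out[[i]] <- vapply(as.integer(hits), function(p) {
      extractWindow(proteome, names(proteome)[i], p, width)
    }, character(1L))
  }
  unlist(out, use.names = FALSE)
}

#' Upper-tail binomial probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p_0)}; the enrichment test
#' applied to each candidate (position, residue) pair during motif
#' extraction.
#'
#' @param k observed count (0..n).
#' @param n number of trials.
#' @param p0 success probability under the null.
#' @return The tail probability.
#' @export
binomialTail <- function(k, n, p0) {
  if (k < 0 || n < 0 || k > n) stop("require 0 <= k <= n")
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (k == 0) return(1.0)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

## One motif-extraction round for a fixed central residue. fg/bg are
## character matrices (windows x width). Returns NULL or a list with the
## fixed pairs and the row indices (into fg) of matching windows.
.motifxExtractOne <- function(fg, bg, width, minOcc, significance) {
  center_col <- (width + 1L) %/% 2L
  free_cols <- setdiff(seq_len(width), center_col)
  fixed_pos <- integer(0)
  fixed_res <- character(0)
  keep_fg <- seq_len(nrow(fg))
  cur_fg <- fg
  cur_bg <- bg
  repeat {
    if (nrow(cur_bg) == 0L || nrow(cur_fg) == 0L) break
    cand_cols <- setdiff(free_cols, posToCol(fixed_pos, width))
    best <- NULL
    for (col in cand_cols) {
      fg_col <- cur_fg[, col]
      bg_col <- cur_bg[, col]
      fg_ok <- fg_col != PAD_CHAR
      bg_ok <- bg_col != PAD_CHAR
      n <- sum(fg_ok)
      bg_n <- sum(bg_ok)
      if (n == 0L || bg_n == 0L) next
      fg_tab <- table(fg_col[fg_ok])
      bg_tab <- table(bg_col[bg_ok])
      for (res in names(fg_tab)) {
        k <- as.integer(fg_tab[[res]])
        if (k < minOcc) next
        p0 <- if (res %in% names(bg_tab)) bg_tab[[res]] / bg_n else 0
        p <- binomialTail(k, n, p0)
        if (p > significance) next
        pos <- col - center_col
        if (is.null(best) ||
            p < best$p ||
            (p == best$p && (k > best$k ||
              (k == best$k && (abs(pos) < abs(best$pos) ||
                (abs(pos) == abs(best$pos) && res < best$res)))))) {
          best <- list(p = p, k = k, pos = pos, res = res, col = col)
        }
      }
    }
    if (is.null(best)) break
    fixed_pos <- c(fixed_pos, best$pos)
    fixed_res <- c(fixed_res, best$res)
    match_fg <- cur_fg[, best$col] == best$res
    match_bg <- cur_bg[, best$col] == best$res
    keep_fg <- keep_fg[match_fg]
    cur_fg <- cur_fg[match_fg, , drop = FALSE]
    cur_bg <- cur_bg[match_bg, , drop = FALSE]
  }
  if (length(fixed_pos) == 0L || length(keep_fg) < minOcc) return(NULL)
  ord <- order(fixed_pos)
  list(fixed = data.frame(pos = as.integer(fixed_pos[ord]),
                          residue = fixed_res[ord],
                          stringsAsFactors = FALSE),
       members = keep_fg)
}

#' Partition aligned windows into motif modules
#'
#' Iterative greedy extraction per central residue: the candidate (position,
#' residue) pair with the smallest binomial tail probability (foreground
#' count vs the running background frequency) is fixed if its p-value is at
#' most \code{significance} and its count at least \code{minOccurrences};
#' non-matching windows are then removed from both foreground and background
#' and the search repeats. When no pair qualifies, the motif is emitted if at
#' least one position is fixed and at least \code{minOccurrences} foreground
#' windows match, those windows are removed from the original foreground,
#' and extraction restarts against the full background. Pad characters
#' (\code{'-'}) never count as residue occurrences and are excluded from the
#' trial count at their position. Ties on p-value are broken by larger
#' count, then smaller \code{|position|}, then alphabetical residue.
#'
#' @param windows character vector of foreground windows (all one width,
#'   centered on a central residue).
#' @param ids identifiers parallel to \code{windows} (default positional).
#' @param background character vector of background windows (same width).
#' @param params see \code{\link{motifParams}}.
#' @return List with \code{motifs} (list of lists: \code{central},
#'   \code{fixed} data.frame, \code{ids}, \code{windows}) and
#'   \code{unassigned} (ids not claimed by any motif).
#' @export
motifxPartition <- function(windows, ids = as.character(seq_along(windows)),
                            background, params = motifParams()) {
  if (length(background) == 0L) stop("background window set is empty")
  if (length(windows) != length(ids)) stop("ids must parallel windows")
  width <- params$width
  center_col <- (width + 1L) %/% 2L
  motifs <- list()
  unassigned <- character(0)
  bgM_all <- windowMatrix(background, width)
  bg_center <- bgM_all[, center_col]
  if (length(windows) == 0L) {
    return(list(motifs = motifs, unassigned = unassigned))
  }
  fgM_all <- windowMatrix(windows, width)
  fg_center <- fgM_all[, center_col]
  for (ctr in params$centralResidues) {
    fg_idx <- which(fg_center == ctr)
    bgM <- bgM_all[bg_center == ctr, , drop = FALSE]
    repeat {
      if (length(fg_idx) < params$minOccurrences) break
      res <- .motifxExtractOne(fgM_all[fg_idx, , drop = FALSE], bgM, width,
                               params$minOccurrences, params$significance)
      if (is.null(res)) break
      member_idx <- fg_idx[res$members]
      motifs[[length(motifs) + 1L]] <-
        list(central = ctr, fixed = res$fixed,
             ids = ids[member_idx], windows = windows[member_idx])
      fg_idx <- setdiff(fg_idx, member_idx)
    }
    unassigned <- c(unassigned, ids[fg_idx])
  }
  ## windows centered on residues outside centralResidues are never assigned
  other <- which(!fg_center %in% params$centralResidues)
  list(motifs = motifs, unassigned = c(unassigned, ids[other]))
}

#' Build motif modules per response class
#'
#' Runs \code{\link{motifxPartition}} separately on the peptides of each
#' non-\code{none} class (foregrounds split by central residue inside the
#' partitioner) against the proteome-wide background, and wraps the results
#' as \linkS4class{MotifModule} objects with deterministic identifiers
#' \code{"<class>.<k>"}.
#'
#' @param peptides a \linkS4class{PhosphoPeptideSet}.
#' @param classes data.frame from \code{\link{classifyPeptides}} (columns
#'   \code{peptide_id}, \code{class}).
#' @param proteome named character vector of protein sequences.
#' @param params see \code{\link{motifParams}}.
#' @return List of \linkS4class{MotifModule}.
#' @export
buildModules <- function(peptides, classes, proteome, params = motifParams()) {
  bg <- backgroundWindows(proteome, params$centralResidues, params$width)
  info <- peptideInfo(peptides)
  cls <- classes$class[match(info$peptide_id, classes$peptide_id)]
  modules <- list()
  for (cl in c("A_inc", "A_dec", "B_inc", "B_dec")) {
    sel <- which(cls == cl)
    if (length(sel) == 0L) next
    part <- motifxPartition(info$window[sel], info$peptide_id[sel], bg, params)
    for (i in seq_along(part$motifs)) {
      m <- part$motifs[[i]]
      pep_idx <- match(m$ids, info$peptide_id)
      modules[[length(modules) + 1L]] <- new("MotifModule",
        moduleId = paste0(cl, ".", i),
        classLabel = cl, central = m$central, fixed = m$fixed,
        peptideIds = m$ids,
        proteinIds = sort(unique(info$protein_id[pep_idx])),
        windows = m$windows, width = params$width)
    }
  }
  modules
}
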