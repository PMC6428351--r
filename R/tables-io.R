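# Readers and writers for the pipeline's tabular formats: peptide tables,
# interaction edge lists, kinase spot-array intensities, proteome FASTA,
# Cytoscape SIF export, and the run manifest.

#' Read a phospho-peptide table
#'
#' The table is TSV with header columns \code{peptide_id}, \code{protein_id},
#' \code{site_pos}, \code{window}, and one fold-change column per
#' strain/replicate named \code{"<strain>_rep<k>_log2fc"}. Rows whose window
#' is not 13 characters or whose central residue is not S/T/Y are rejected
#' with a message; the central residue is taken from the window center.
#'
#' @param path path to the TSV file.
#' @param strains character vector of strain identifiers in panel order.
#' @return A \linkS4class{PhosphoPeptideSet} in file row order.
#' @export
readPeptideTable <- function(path, strains) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  need <- c("peptide_id", "protein_id", "site_pos", "window")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peptide table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fc_cols <- list()
  for (s in strains) {
    cols <- grep(paste0("^", s, "_rep[0-9]+_log2fc$"), names(df), value = TRUE)
    if (length(cols) == 0L) {
      stop("peptide table is missing fold-change columns for strain: ", s)
    }
    reps <- as.integer(sub("_log2fc$", "", sub(paste0("^", s, "_rep"), "", cols)))
    fc_cols[[s]] <- cols[order(reps)]
  }
  nrep <- unique(lengths(fc_cols))
  if (length(nrep) != 1L) {
    stop("strains have differing replicate counts: ",
         paste(lengths(fc_cols), collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("peptide table has a header but no rows")
  }
  fc <- matrix(NA_real_, nrow = nrow(df), ncol = nrep * length(strains),
               dimnames = list(NULL, as.vector(vapply(strains, function(s)
                 paste(s, seq_len(nrep), sep = "."), character(nrep)))))
  for (s in strains) {
    for (r in seq_len(nrep)) {
      raw <- df[[fc_cols[[s]][r]]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
      if (length(bad)) {
        stop("non-numeric fold-change in column ", fc_cols[[s]][r],
             " at row ", bad[1L])
      }
      fc[, paste(s, r, sep = ".")] <- val
    }
  }
  window <- toupper(df$window)
  central <- ifelse(nchar(window) == 13L, substr(window, 7L, 7L), "")
  ok <- nchar(window) == 13L & central %in% c("S", "T", "Y")
  if (any(!ok)) {
    message(sum(!ok), " row(s) rejected (bad window length or central residue)")
  }
  info <- data.frame(peptide_id = df$peptide_id, protein_id = df$protein_id,
                     site_pos = suppressWarnings(as.integer(df$site_pos)),
                     central = central, window = window,
                     stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(info) <- NULL
  PhosphoPeptideSet(info, fc[ok, , drop = FALSE], strains)
}

#' Write a phospho-peptide table
#'
#' Inverse of \code{\link{readPeptideTable}}. Fold-changes are written in
#' full precision (17 digits) so read-after-write reproduces the in-memory
#' values exactly.
#'
#' @param peptides a \linkS4class{PhosphoPeptideSet}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePeptideTable <- function(peptides, path) {
  info <- peptideInfo(peptides)
  fc <- foldChanges(peptides)
  strains <- strainNames(peptides)
  nrep <- peptides@nReplicates
  out <- info[, c("peptide_id", "protein_id", "site_pos", "window")]
  for (s in strains) {
    for (r in seq_len(nrep)) {
      out[[paste0(s, "_rep", r, "_log2fc")]] <-
        format(fc[, paste(s, r, sep = ".")], digits = 17, trim = TRUE,
               scientific = FALSE)
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a background interaction network
#'
#' TSV with columns \code{source}, \code{target}, \code{directed} (0/1) and
#' \code{etype} (\code{ppi} or \code{kinase_substrate}). Undirected edges are
#' canonicalized (endpoints sorted), exact duplicates merged, and self-loops
#' dropped with a warning.
#'
#' @param path path to the edge-list TSV.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("source", "target", "directed", "etype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("network file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$etype), c("ppi", "kinase_substrate"))
  if (length(bad)) {
    stop("unknown etype value(s): ", paste(bad, collapse = ", "))
  }
  df$directed <- df$directed %in% c("1", "TRUE", "true")
  InteractionNetwork(df)
}

#' Write an interaction network edge list
#' @param network an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeNetwork <- function(network, path) {
  e <- networkEdges(network)
  e$directed <- as.integer(e$directed)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase spot-array intensity library
#'
#' Long-format TSV with columns \code{kinase}, \code{position},
#' \code{residue}, \code{intensity}: the normalized, background-corrected
#' spot intensity for each amino acid at each position relative to the
#' phospho-acceptor. Every (kinase, position) must have exactly one row per
#' amino acid; duplicates and negative intensities are format errors.
#'
#' @param path path to the TSV.
#' @return A \linkS4class{KinaseLibrary} with position labels sorted
#'   ascending.
#' @export
readKinaseIntensities <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("kinase", "position", "residue", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("intensity file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$intensity <- as.numeric(df$intensity)
  if (any(is.na(df$intensity))) stop("non-numeric intensity value")
  neg <- which(df$intensity < 0)
  if (length(neg)) {
    stop("negative intensity for kinase ", df$kinase[neg[1L]],
         " at position ", df$position[neg[1L]])
  }
  key <- paste(df$kinase, df$position, df$residue)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate intensity cell: ", d)
  }
  entries <- list()
  for (kn in unique(df$kinase)) {
    sub <- df[df$kinase == kn, , drop = FALSE]
    positions <- sort(unique(sub$position))
    m <- matrix(NA_real_, nrow = 20L, ncol = length(positions),
                dimnames = list(AA20, positions))
    idx <- cbind(match(sub$residue, AA20), match(sub$position, positions))
    if (anyNA(idx[, 1L])) {
      stop("unknown residue for kinase ", kn, ": ",
           sub$residue[which(is.na(idx[, 1L]))[1L]])
    }
    m[idx] <- sub$intensity
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing residue ", AA20[miss[1L]], " for kinase ", kn,
           " at position ", positions[miss[2L]])
    }
    entries[[kn]] <- m
  }
  KinaseLibrary(entries)
}

#' Write a kinase intensity library
#' @param library a \linkS4class{KinaseLibrary}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeKinaseIntensities <- function(library, path) {
  rows <- lapply(kinaseNames(library), function(kn) {
    m <- intensityMatrix(library, kn)
    data.frame(kinase = kn,
               position = rep(as.integer(colnames(m)), each = nrow(m)),
               residue = rep(rownames(m), times = ncol(m)),
               intensity = format(as.vector(m), digits = 17, trim = TRUE,
                                  scientific = FALSE),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a proteome FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate identifiers and empty records are
#' format errors.
#'
#' @param path path to the FASTA file.
#' @return A named character vector of protein sequences.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate protein identifier: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence record: ", ids[which(nchar(seqs) == 0L)[1L]])
  }
  names(seqs) <- ids
  seqs
}

#' Write a proteome FASTA
#' @param proteome named character vector of sequences.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Write a Cytoscape SIF file
#'
#' One line \code{source<TAB>relation<TAB>target} per edge, in input order;
#' the file ends with a newline (an empty edge set yields an empty file).
#'
#' @param edges data.frame with columns \code{source}, \code{relation},
#'   \code{target}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSIF <- function(edges, path) {
  if (nrow(edges) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  vals <- c(edges$source, edges$relation, edges$target)
  if (any(grepl("\t", vals, fixed = TRUE))) {
    stop("node or relation names must not contain tabs")
  }
  if (any(edges$relation == "" | grepl("\\s", edges$relation))) {
    stop("relation must be a non-empty token without whitespace")
  }
  writeLines(paste(edges$source, edges$relation, edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Each element of \code{results} is written as
#' \code{<out_dir>/<name>.tsv} with deterministic column order, rows sorted
#' by module, identifier and score where those columns exist, and floats
#' rendered with 6 significant digits. A \code{run_manifest.json} records the
#' configuration hash, seed, input checksums, and md5 checksums of every
#' written table, so two runs with identical inputs and seed are
#' byte-identical.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config list of configuration values recorded (hashed) in the
#'   manifest.
#' @param seed integer seed recorded in the manifest.
#' @param input_files named character vector of input paths to checksum.
#' @return Invisibly, the manifest as a list.
#' @export
writeResultTables <- function(results, out_dir, config = list(), seed = NA,
                              input_files = character(0)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    sort_cols <- intersect(c("module_id", "class", "protein_id", "kinase",
                             "peptide_id", "feature_id", "set_name",
                             "source", "target"), names(df))
    if (length(sort_cols) && nrow(df) > 1L) {
      df <- df[do.call(order, df[sort_cols]), , drop = FALSE]
    }
    num_cols <- names(df)[vapply(df, is.double, logical(1L))]
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    writeTSV(df, path, float_cols = num_cols)
    files <- c(files, path)
  }
  cfg_str <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  cfg_tmp <- tempfile()
  writeLines(cfg_str, cfg_tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_tmp)),
    seed = seed,
    inputs = as.list(setNames(unname(tools::md5sum(input_files)),
                              basename(input_files))),
    outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Annotation sets for enrichment
#'
#' @param sets named list of character vectors (feature identifiers per set).
#' @param background character vector of all feature identifiers; defaults to
#'   the union of the sets. Every annotated feature must be in the
#'   background.
#' @return A list with elements \code{sets} and \code{background}.
#' @export
annotationSets <- function(sets, background = NULL) {
  sets <- lapply(sets, unique)
  if (is.null(background)) background <- unique(unlist(sets, use.names = FALSE))
  background <- unique(background)
  stray <- setdiff(unlist(sets, use.names = FALSE), background)
  if (length(stray)) {
    stop("annotated feature(s) outside background: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  list(sets = sets, background = background)
}

#' Read annotation sets from a two-column TSV
#'
#' @param path TSV with columns \code{set_name}, \code{feature_id}.
#' @param background optional character vector of background features.
#' @return See \code{\link{annotationSets}}.
#' @export
readAnnotationSets <- function(path, background = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("set_name", "feature_id") %in% names(df))) {
    stop("annotation file needs columns set_name, feature_id")
  }
  annotationSets(split(df$feature_id, df$set_name), background)
}
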