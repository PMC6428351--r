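# Ground-truthed synthetic scenarios: a proteome, a kinase specificity
# library, an interaction network with planted kinase->substrate edges, and
# a multi-strain peptide table whose fold-change classes and motifs are
# known. Every downstream stage of the pipeline can be benchmarked against
# the planted truth without external data.

#' Simulation parameters
#'
#' Defaults describe the reference benchmark scenario: 4 planted kinases
#' with 40 substrates each, 400 decoy peptides, an 800-protein network with
#' Erdos-Renyi background edges at probability 0.01, sharp kinase motifs
#' (Dirichlet concentration 0.05), 3 strains x 2 replicates, a log2 step of
#' 1.0 between consecutive strains for progressive peptides, and replicate
#' noise of 0.2 log2 units.
#'
#' @param nKinases number of planted kinases.
#' @param substratesPerKinase substrate peptides per kinase.
#' @param nDecoyPeptides decoy peptides with uniform-random windows and no
#'   planted response.
#' @param nNetworkNodes total network proteins (>= kinases + substrates +
#'   decoys).
#' @param backgroundEdgeProb Erdos-Renyi edge probability for undirected
#'   background edges.
#' @param pwmSharpness symmetric Dirichlet concentration for kinase PWM
#'   columns; smaller is sharper (default 0.05).
#' @param nStrains strains in the panel (default 3).
#' @param nReplicates replicates per strain (default 2).
#' @param classEffect log2 step between consecutive strains for progressive
#'   peptides (default 1.0).
#' @param noiseSd replicate noise standard deviation, log2 units (default
#'   0.2).
#' @param plantedClassMix named proportions over
#'   \code{c("A_inc","A_dec","B_inc","B_dec","none")} assigned to planted
#'   kinases (each kinase's substrates share its class); must sum to 1.
#' @param seed integer RNG seed; the whole scenario is a pure function of
#'   these parameters.
#' @return A validated parameter list.
#' @export
simParams <- function(nKinases = 4L, substratesPerKinase = 40L,
                      nDecoyPeptides = 400L, nNetworkNodes = 800L,
                      backgroundEdgeProb = 0.01, pwmSharpness = 0.05,
                      nStrains = 3L, nReplicates = 2L, classEffect = 1.0,
                      noiseSd = 0.2,
                      plantedClassMix = c(A_inc = 0.25, A_dec = 0.25,
                                          B_inc = 0.25, B_dec = 0.25),
                      seed = 1L) {
  if (abs(sum(plantedClassMix) - 1) > 1e-9) stop("plantedClassMix must sum to 1")
  if (any(c(nKinases, substratesPerKinase, nDecoyPeptides, nNetworkNodes) < 0)) {
    stop("counts must be >= 0")
  }
  if (backgroundEdgeProb < 0 || backgroundEdgeProb > 1) {
    stop("backgroundEdgeProb must be in [0, 1]")
  }
  if (pwmSharpness <= 0) stop("pwmSharpness must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  list(nKinases = as.integer(nKinases),
       substratesPerKinase = as.integer(substratesPerKinase),
       nDecoyPeptides = as.integer(nDecoyPeptides),
       nNetworkNodes = as.integer(nNetworkNodes),
       backgroundEdgeProb = backgroundEdgeProb,
       pwmSharpness = pwmSharpness,
       nStrains = as.integer(nStrains),
       nReplicates = as.integer(nReplicates),
       classEffect = classEffect, noiseSd = noiseSd,
       plantedClassMix = plantedClassMix, seed = as.integer(seed))
}

#' Sample a random PWM from a symmetric Dirichlet
#'
#' Each column is an independent draw from a symmetric Dirichlet over the 20
#' amino acids with concentration \code{sharpness}; small concentrations
#' give sharp, nearly point-mass columns, large concentrations approach the
#' uniform distribution. Uses the current RNG stream.
#'
#' @param nPositions number of flanking positions (>= 1); position labels
#'   are \code{-h..-1, 1..h} for \code{nPositions = 2h}, or
#'   \code{positions} may be given explicitly.
#' @param sharpness Dirichlet concentration (> 0).
#' @param positions optional explicit integer positions (0 excluded).
#' @return A \linkS4class{PWM} with pseudocount 0.
#' @export
samplePWM <- function(nPositions, sharpness, positions = NULL) {
  if (sharpness <= 0) stop("sharpness must be > 0")
  if (nPositions < 1L) stop("nPositions must be >= 1")
  if (is.null(positions)) {
    h <- ceiling(nPositions / 2)
    positions <- setdiff(seq.int(-h, h), 0L)[seq_len(nPositions)]
  }
  g <- matrix(rgamma(20L * nPositions, shape = sharpness), nrow = 20L)
  ## guard against total underflow in a very sharp column
  zero <- colSums(g) == 0
  if (any(zero)) g[cbind(sample.int(20L, sum(zero), TRUE), which(zero))] <- 1
  .newPWM(sweep(g, 2L, colSums(g), "/"), positions, 0)
}

## Erdos-Renyi G(n, p): sample the edge count from Binomial(C(n,2), p), then
## a uniform edge set of that size (equivalent to independent pair coins).
.sampleERPairs <- function(nodes, prob) {
  n <- length(nodes)
  npairs <- n * (n - 1) / 2
  if (npairs == 0 || prob == 0) {
    return(data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- rbinom(1L, npairs, prob)
  if (m == 0) {
    return(data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- sample(npairs, m) - 1
  ## map linear index to (i, j), i < j, 0-based rows of the upper triangle
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  j <- idx - i * n + i * (i + 1) / 2 + i + 1
  data.frame(source = nodes[i + 1], target = nodes[j + 1],
             stringsAsFactors = FALSE)
}

#' Generate an interaction network with planted kinase-substrate edges
#'
#' Undirected \code{ppi} background edges are drawn Erdos-Renyi among all
#' nodes at \code{backgroundEdgeProb}; every planted kinase->substrate pair
#' adds a directed \code{kinase_substrate} edge. Uses the current RNG
#' stream.
#'
#' @param nodes character vector of all network proteins.
#' @param plantedEdges data.frame with columns \code{source} (kinase) and
#'   \code{target} (substrate protein).
#' @param backgroundEdgeProb Erdos-Renyi probability.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
generateNetwork <- function(nodes, plantedEdges, backgroundEdgeProb) {
  bg <- .sampleERPairs(nodes, backgroundEdgeProb)
  edges <- rbind(
    if (nrow(bg)) data.frame(bg, directed = FALSE, etype = "ppi",
                             stringsAsFactors = FALSE),
    if (nrow(plantedEdges)) data.frame(source = plantedEdges$source,
                                       target = plantedEdges$target,
                                       directed = TRUE,
                                       etype = "kinase_substrate",
                                       stringsAsFactors = FALSE))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        directed = logical(0), etype = character(0),
                        stringsAsFactors = FALSE)
  }
  InteractionNetwork(edges, nodes = nodes)
}

## Sample n windows column-wise from a PWM (flanking positions), with the
## given central residue at the center. Returns width-13 uppercase windows.
.sampleWindows <- function(pwm, n, central, width = 13L) {
  positions <- flankPositions(width)
  m <- pwmMatrix(pwm)
  chars <- matrix(central, nrow = n, ncol = width)
  for (pos in positions) {
    col_lab <- as.character(pos)
    probs <- if (col_lab %in% colnames(m)) m[, col_lab] else rep(1 / 20, 20L)
    chars[, posToCol(pos, width)] <- sample(AA20, n, replace = TRUE,
                                            prob = probs)
  }
  apply(chars, 1L, paste, collapse = "")
}

## Class mean profiles across the strain panel (first -> last strain).
.classProfile <- function(label, nStrains, effect) {
  base <- switch(label,
    A_inc = seq.int(0L, nStrains - 1L) * effect,
    A_dec = -seq.int(0L, nStrains - 1L) * effect,
    B_inc = c(rep(0, nStrains - 1L), (nStrains - 1L) * effect),
    B_dec = c(rep(0, nStrains - 1L), -(nStrains - 1L) * effect),
    none = rep(0, nStrains),
    stop("unknown class label: ", label))
  base
}

## Largest-remainder apportionment of n items to the named proportions.
.apportion <- function(n, proportions) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), names(proportions))
}

#' Generate a complete ground-truthed scenario
#'
#' Produces an internally consistent bundle: a proteome whose sequences
#' embed every peptide window at its site position, a kinase intensity
#' library (the sampled PWMs rescaled to a 0-100 intensity scale), an
#' interaction network with planted directed kinase->substrate edges over an
#' Erdos-Renyi background, a peptide table with class-structured replicate
#' fold-changes, and the ground truth (kinase and class of every peptide,
#' planted edges).
#'
#' Planted kinases are assigned response classes by largest-remainder
#' apportionment of \code{plantedClassMix}; all substrates of a kinase share
#' its class, their windows are sampled column-wise from the kinase's PWM
#' with the kinase's fixed central residue (alternating S/T across kinases).
#' Decoy peptides have uniform-random windows, class \code{none}, and flat
#' profiles. Replicate fold-changes are the class mean profile plus
#' \code{Normal(0, noiseSd)} noise.
#'
#' @param params see \code{\link{simParams}}.
#' @return List with elements \code{proteome}, \code{kinaseLibrary},
#'   \code{network}, \code{peptides} (\linkS4class{PhosphoPeptideSet}),
#'   \code{truth} (list: \code{kinaseOfPeptide}, \code{trueClass},
#'   \code{plantedEdges}, \code{kinasePWMs}, \code{kinaseClass},
#'   \code{regulators}), and \code{params}.
#' @export
generateScenario <- function(params = simParams()) {
  set.seed(params$seed)
  nk <- params$nKinases
  spk <- params$substratesPerKinase
  kin_names <- sprintf("KIN%02d", seq_len(nk))
  sub_names <- sprintf("SUB%04d", seq_len(nk * spk))
  dec_names <- sprintf("DEC%04d", seq_len(params$nDecoyPeptides))
  n_named <- nk + length(sub_names) + length(dec_names)
  if (params$nNetworkNodes < n_named) {
    stop("nNetworkNodes must be at least kinases + substrates + decoys (",
         n_named, ")")
  }
  fill_names <- if (params$nNetworkNodes > n_named) {
    sprintf("PRO%04d", seq_len(params$nNetworkNodes - n_named))
  } else character(0)
  all_nodes <- c(kin_names, sub_names, dec_names, fill_names)

  ## kinase PWMs, central residues, classes
  kin_pwms <- setNames(lapply(seq_len(nk), function(i)
    samplePWM(12L, params$pwmSharpness, positions = flankPositions(13L))),
    kin_names)
  kin_central <- setNames(rep(c("S", "T"), length.out = nk), kin_names)
  class_counts <- .apportion(nk, params$plantedClassMix)
  kin_class <- setNames(rep(names(class_counts), class_counts), kin_names)

  ## peptide table: one peptide per substrate protein, then decoys
  pep_protein <- c(sub_names, dec_names)
  pep_id <- paste0("pep_", pep_protein)
  pep_kinase <- c(rep(kin_names, each = spk),
                  rep(NA_character_, length(dec_names)))
  pep_class <- c(rep(unname(kin_class), each = spk),
                 rep("none", length(dec_names)))
  windows <- character(length(pep_id))
  for (kn in kin_names) {
    idx <- which(pep_kinase == kn)
    if (length(idx)) {
      windows[idx] <- .sampleWindows(kin_pwms[[kn]], length(idx),
                                     kin_central[[kn]])
    }
  }
  dec_idx <- which(is.na(pep_kinase))
  if (length(dec_idx)) {
    dec_centrals <- sample(c("S", "T"), length(dec_idx), replace = TRUE)
    flat <- .newPWM(matrix(1 / 20, 20L, 12L), flankPositions(13L), 0)
    dec_w <- .sampleWindows(flat, length(dec_idx), "S")
    substr(dec_w, 7L, 7L) <- dec_centrals
    windows[dec_idx] <- dec_w
  }

  ## proteome: every network protein gets a sequence; peptide windows are
  ## embedded at an interior site so no window is padded
  prot_len <- 61L
  site_pos <- rep(31L, length(pep_id))
  proteome <- setNames(vapply(all_nodes, function(p)
    paste(sample(AA20, prot_len, replace = TRUE), collapse = ""),
    character(1L)), all_nodes)
  for (i in seq_along(pep_id)) {
    seq <- proteome[[pep_protein[i]]]
    substr(seq, site_pos[i] - 6L, site_pos[i] + 6L) <- windows[i]
    proteome[[pep_protein[i]]] <- seq
  }
  ## re-read windows from the proteome so table and proteome agree exactly
  windows <- vapply(seq_along(pep_id), function(i)
    substr(proteome[[pep_protein[i]]], site_pos[i] - 6L, site_pos[i] + 6L),
    character(1L))

  ## replicate fold-changes
  strains <- sprintf("strain%d", seq_len(params$nStrains))
  ncols <- params$nStrains * params$nReplicates
  fc <- matrix(NA_real_, nrow = length(pep_id), ncol = ncols,
               dimnames = list(NULL, as.vector(vapply(strains, function(s)
                 paste(s, seq_len(params$nReplicates), sep = "."),
                 character(params$nReplicates)))))
  for (i in seq_along(pep_id)) {
    prof <- .classProfile(pep_class[i], params$nStrains, params$classEffect)
    vals <- rep(prof, each = params$nReplicates) +
      rnorm(ncols, 0, params$noiseSd)
    fc[i, as.vector(vapply(strains, function(s)
      paste(s, seq_len(params$nReplicates), sep = "."),
      character(params$nReplicates)))] <- vals
  }

  peptides <- PhosphoPeptideSet(
    data.frame(peptide_id = pep_id, protein_id = pep_protein,
               site_pos = site_pos, central = substr(windows, 7L, 7L),
               window = windows, stringsAsFactors = FALSE),
    fc, strains)

  planted <- data.frame(source = rep(kin_names, each = spk),
                        target = sub_names, stringsAsFactors = FALSE)
  network <- generateNetwork(all_nodes, planted, params$backgroundEdgeProb)

  ## intensity library: sampled PWMs on a 0-100 intensity scale
  lib <- KinaseLibrary(lapply(kin_pwms, function(p) {
    m <- pwmMatrix(p) * 100
    dimnames(m) <- list(AA20, as.character(pwmPositions(p)))
    m
  }))

  list(proteome = proteome, kinaseLibrary = lib, network = network,
       peptides = peptides,
       truth = list(
         kinaseOfPeptide = setNames(pep_kinase, pep_id),
         trueClass = setNames(pep_class, pep_id),
         plantedEdges = planted,
         kinasePWMs = kin_pwms,
         kinaseClass = kin_class,
         kinaseCentral = kin_central,
         regulators = kin_names),
       params = params)
}

#' Write a scenario to disk in the pipeline's input formats
#'
#' Writes \code{peptides.tsv}, \code{network.tsv},
#' \code{kinase_intensities.tsv}, \code{proteome.fasta},
#' \code{regulators.txt}, \code{ground_truth.tsv} and
#' \code{sim_config.json} into \code{dir}.
#'
#' @param scenario from \code{\link{generateScenario}}.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    peptides = file.path(dir, "peptides.tsv"),
    network = file.path(dir, "network.tsv"),
    kinase_intensities = file.path(dir, "kinase_intensities.tsv"),
    proteome = file.path(dir, "proteome.fasta"),
    regulators = file.path(dir, "regulators.txt"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    sim_config = file.path(dir, "sim_config.json"))
  writePeptideTable(scenario$peptides, paths[["peptides"]])
  writeNetwork(scenario$network, paths[["network"]])
  writeKinaseIntensities(scenario$kinaseLibrary, paths[["kinase_intensities"]])
  writeProteome(scenario$proteome, paths[["proteome"]])
  writeLines(scenario$truth$regulators, paths[["regulators"]])
  gt <- data.frame(peptide_id = names(scenario$truth$trueClass),
                   true_class = unname(scenario$truth$trueClass),
                   kinase = ifelse(is.na(scenario$truth$kinaseOfPeptide), "",
                                   scenario$truth$kinaseOfPeptide),
                   stringsAsFactors = FALSE)
  write.table(gt, paths[["ground_truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(scenario$params, paths[["sim_config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
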