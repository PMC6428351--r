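# End-to-end orchestration: classify -> motif modules -> shared interactors
# -> directionality -> kinase matching -> regulator network assembly, with
# deterministic outputs and a run manifest.

#' Pipeline configuration
#'
#' @param peptides path to the peptide table TSV.
#' @param network path to the interaction edge-list TSV.
#' @param proteome path to the proteome FASTA.
#' @param kinaseIntensities path to the kinase spot-array intensity TSV.
#' @param regulators path to a text file of known kinase/phosphatase
#'   identifiers, one per line.
#' @param outDir output directory.
#' @param strains panel strain identifiers (progenitor -> evolved) as they
#'   appear in the peptide table columns.
#' @param classification see \code{\link{classificationParams}}.
#' @param motif see \code{\link{motifParams}}.
#' @param enrichment see \code{\link{enrichmentParams}}.
#' @param match see \code{\link{matchParams}} (its \code{rngSeed} is
#'   overridden by a substream of \code{seed}).
#' @param seed master seed; per-stage seeds are derived from it so adding
#'   randomness in one stage does not perturb another.
#' @return A validated configuration list.
#' @export
pipelineConfig <- function(peptides, network, proteome, kinaseIntensities,
                           regulators, outDir,
                           strains = c("Y22-3", "Y127", "Y128"),
                           classification = NULL, motif = motifParams(),
                           enrichment = enrichmentParams(),
                           match = matchParams(), seed = 1L) {
  if (is.null(classification)) {
    classification <- classificationParams(strainOrder = strains)
  }
  paths <- c(peptides = peptides, network = network, proteome = proteome,
             kinaseIntensities = kinaseIntensities, regulators = regulators)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  list(paths = as.list(paths), outDir = outDir, strains = strains,
       classification = classification, motif = motif,
       enrichment = enrichment, match = match, seed = as.integer(seed))
}

#' Assemble the regulator network
#'
#' Nodes are regulators, modules and member proteins; edges are
#' \code{regulator -regulates-> module} and
#' \code{module -contains-> protein}. A regulator edge requires a
#' significant shared interactor that passed the directionality filter and,
#' when the regulator is a kinase present in the specificity library, a
#' passing specificity match; phosphatases (and other regulators without a
#' library entry) are retained on interaction evidence alone. Rejected
#' kinase candidates (failed match) are returned separately.
#'
#' @param modules list of \linkS4class{MotifModule}.
#' @param regulators data.frame from \code{\link{directionalityFilter}}.
#' @param matches data.frame from \code{\link{matchKinases}}.
#' @param libraryKinases character vector of kinases present in the
#'   specificity library.
#' @return List with \code{nodes} (data.frame: \code{id}, \code{type},
#'   \code{class}, \code{motif}), \code{edges} (data.frame: \code{source},
#'   \code{relation}, \code{target}) and \code{rejected} (kinase candidates
#'   failing the match).
#' @export
assembleNetwork <- function(modules, regulators, matches, libraryKinases) {
  mod_ids <- vapply(modules, moduleId, character(1L))
  if (nrow(regulators) && !all(regulators$module_id %in% mod_ids)) {
    stop("regulator table references unknown module(s): ",
         paste(setdiff(regulators$module_id, mod_ids), collapse = ", "))
  }
  match_key <- paste(matches$kinase, matches$module_id)
  reg_edges <- list()
  rejected <- list()
  if (nrow(regulators)) {
    for (i in seq_len(nrow(regulators))) {
      reg <- regulators$protein_id[i]
      mid <- regulators$module_id[i]
      needs_match <- reg %in% libraryKinases
      ok <- TRUE
      if (needs_match) {
        hit <- match(paste(reg, mid), match_key)
        ok <- !is.na(hit) && isTRUE(matches$passed[hit])
      }
      if (ok) {
        reg_edges[[length(reg_edges) + 1L]] <-
          data.frame(source = reg, relation = "regulates", target = mid,
                     stringsAsFactors = FALSE)
      } else {
        rejected[[length(rejected) + 1L]] <-
          data.frame(kinase = reg, module_id = mid,
                     reason = "match_fdr_failed", stringsAsFactors = FALSE)
      }
    }
  }
  contain_edges <- lapply(modules, function(m) {
    data.frame(source = moduleId(m), relation = "contains",
               target = memberProteins(m), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(reg_edges, contain_edges))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), relation = character(0),
                        target = character(0), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$relation, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  node_rows <- rbind(
    data.frame(id = unique(edges$source[edges$relation == "regulates"]),
               type = "regulator", class = "", motif = "",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(modules, function(m)
      data.frame(id = moduleId(m), type = "module", class = classLabel(m),
                 motif = motifString(m), stringsAsFactors = FALSE))),
    data.frame(id = sort(unique(edges$target[edges$relation == "contains"])),
               type = "protein", class = "", motif = "",
               stringsAsFactors = FALSE))
  node_rows <- node_rows[!duplicated(node_rows$id), , drop = FALSE]
  rownames(node_rows) <- NULL
  rej <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(kinase = character(0), module_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(nodes = node_rows, edges = edges, rejected = rej)
}

#' Run the four inference stages on in-memory inputs
#'
#' (1) classify peptides by fold-change pattern, (2) partition each class
#' into phospho-motif modules, (3) find shared-interactor candidates in the
#' background network and filter by directionality, (4) confirm kinase
#' candidates by specificity matching, then assemble the regulator network.
#'
#' @param peptides a \linkS4class{PhosphoPeptideSet}.
#' @param network an \linkS4class{InteractionNetwork}.
#' @param proteome named character vector of protein sequences.
#' @param kinaseLibrary a \linkS4class{KinaseLibrary}.
#' @param regulatorSet character vector of known kinase/phosphatase
#'   identifiers.
#' @param classification,motif,enrichment,match stage parameter lists.
#' @param seed master seed; the matching stage uses a derived substream.
#' @return List with \code{classified}, \code{modulesList}, \code{modules}
#'   (long table), \code{shared_interactors}, \code{regulators},
#'   \code{matches}, \code{rejected}, \code{network} (nodes/edges/rejected).
#' @export
inferRegulators <- function(peptides, network, proteome, kinaseLibrary,
                            regulatorSet,
                            classification = classificationParams(),
                            motif = motifParams(),
                            enrichment = enrichmentParams(),
                            match = matchParams(), seed = 1L) {
  message("stage 1/4: classifying ", length(peptideIds(peptides)), " peptides")
  classified <- classifyPeptides(peptides, classification)
  message("  classes: ",
          paste(names(table(classified$class)), table(classified$class),
                sep = "=", collapse = ", "))

  message("stage 2/4: extracting motif modules")
  modules <- buildModules(peptides, classified, proteome, motif)
  message("  ", length(modules), " module(s)")

  message("stage 3/4: shared-interactor search")
  shared <- findSharedInteractors(network, modules, enrichment)
  message("  ", nrow(shared), " significant shared interactor(s)")
  regulators <- directionalityFilter(shared, regulatorSet, enrichment)
  message("  ", nrow(regulators), " pass the directionality filter")

  message("stage 4/4: kinase specificity matching")
  mparams <- match
  mparams$rngSeed <- stageSeed(seed, "match")
  mod_pwms <- setNames(lapply(modules, modulePWM,
                              pseudocount = mparams$pseudocount),
                       vapply(modules, moduleId, character(1L)))
  lib_kinases <- kinaseNames(kinaseLibrary)
  cand <- split(regulators$protein_id, regulators$module_id)
  cand <- lapply(cand, function(x) intersect(unique(x), lib_kinases))
  cand <- cand[lengths(cand) > 0]
  matches <- matchKinases(mod_pwms[names(cand)], kinaseLibrary, cand, mparams)
  message("  ", sum(matches$passed), " kinase match(es) pass FDR < ",
          mparams$matchFdrThreshold)

  net <- assembleNetwork(modules, regulators, matches, lib_kinases)
  info <- peptideInfo(peptides)
  module_table <- do.call(rbind, c(lapply(modules, function(m)
    data.frame(module_id = moduleId(m), class = classLabel(m),
               motif = motifString(m), peptide_id = memberPeptides(m),
               protein_id = info$protein_id[match(memberPeptides(m),
                                                  info$peptide_id)],
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  if (is.null(module_table)) {
    module_table <- data.frame(module_id = character(0), class = character(0),
                               motif = character(0),
                               peptide_id = character(0),
                               protein_id = character(0),
                               stringsAsFactors = FALSE)
  }

  list(classified = classified, modules = module_table,
       shared_interactors = shared, regulators = regulators,
       matches = matches, rejected = net$rejected,
       network_nodes = net$nodes, network = net, modulesList = modules)
}

#' Run the full regulator-inference pipeline on files
#'
#' Reads the configured inputs, executes \code{\link{inferRegulators}}, and
#' writes per-stage TSV tables (\code{classified}, \code{modules},
#' \code{shared_interactors}, \code{regulators}, \code{matches},
#' \code{rejected}, \code{network_nodes}), a Cytoscape SIF of the regulator
#' network, and a JSON run manifest with input/output checksums. A second
#' run with an identical configuration and seed is byte-identical.
#'
#' @param config see \code{\link{pipelineConfig}}.
#' @return Invisibly, the stage results plus the manifest.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  peptides <- readPeptideTable(config$paths$peptides, config$strains)
  network <- readNetwork(config$paths$network)
  proteome <- readProteome(config$paths$proteome)
  kinase_library <- readKinaseIntensities(config$paths$kinaseIntensities)
  regulator_set <- readLines(config$paths$regulators)
  regulator_set <- regulator_set[nzchar(regulator_set)]

  res <- inferRegulators(peptides, network, proteome, kinase_library,
                         regulator_set,
                         classification = config$classification,
                         motif = config$motif,
                         enrichment = config$enrichment,
                         match = config$match, seed = config$seed)
  tables <- res[c("classified", "modules", "shared_interactors",
                  "regulators", "matches", "rejected", "network_nodes")]
  manifest <- writeResultTables(
    tables, config$outDir,
    config = config[c("strains", "classification", "motif", "enrichment",
                      "match", "seed")],
    seed = config$seed,
    input_files = unlist(config$paths))
  writeSIF(res$network$edges, file.path(config$outDir, "network.sif"))
  invisible(c(res, list(manifest = manifest)))
}
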