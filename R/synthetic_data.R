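# Seeded generators producing inputs with known ground truth for every
# pipeline stage: hit tables, species-tagged gene trees and induction
# expression datasets.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a homology hit table with known membership truth
#'
#' Each query receives one primary hit and a few lower-scoring decoys
#' against a synthetic family-labelled reference. Member queries get a
#' primary hit satisfying the confident-membership rule (identity drawn
#' from U(97, 100), aligned length from U(201, 600), E-value well below
#' the discovery threshold); non-members violate the identity bound, the
#' length bound, both, or carry an E-value above the threshold. The truth
#' records which rule each non-member violates.
#'
#' @param n_queries Number of query proteins (>= 1).
#' @param member_fraction Fraction of queries that are true members.
#' @param seed Integer seed; identical seeds give identical output.
#' @param families Pool of CAZy family labels for the reference.
#' @return List with `hits` (BLAST-tabular-compatible data frame),
#'   `reference` (protein_id/family/characterized/structure_known),
#'   `truth` (query_id/is_member/violation) and `params`.
#' @export
gen_hit_table <- function(n_queries, member_fraction, seed,
                          families = c("GH3", "GH5", "GH7", "GH18",
                                       "CE5", "PL20")) {
  stopifnot(n_queries >= 1, member_fraction >= 0, member_fraction <= 1)
  with_seed(seed, {
    n_mem <- round(member_fraction * n_queries)
    is_mem <- c(rep(TRUE, n_mem), rep(FALSE, n_queries - n_mem))
    qid <- sprintf("q%04d", seq_len(n_queries))
    fam <- sample(families, n_queries, replace = TRUE)
    violation <- rep("none", n_queries)
    identity <- length_aa <- evalue <- numeric(n_queries)
    for (i in seq_len(n_queries)) {
      if (is_mem[i]) {
        identity[i] <- stats::runif(1, 97, 100)
        length_aa[i] <- sample(201:600, 1)
        evalue[i] <- 10^(-stats::runif(1, 12, 50))
      } else {
        violation[i] <- sample(c("identity", "length", "both", "evalue"),
                               1)
        identity[i] <- switch(violation[i],
          identity = , both = stats::runif(1, 40, 96.9),
          stats::runif(1, 97, 100))
        length_aa[i] <- switch(violation[i],
          length = , both = sample(50:200, 1),
          sample(201:600, 1))
        evalue[i] <- if (violation[i] == "evalue")
          10^(-stats::runif(1, 0, 10.9)) else 10^(-stats::runif(1, 12, 50))
      }
    }
    sid <- sprintf("REF_%s_%04d", fam, seq_len(n_queries))
    bitscore <- round(2 * length_aa * identity / 100 +
                        stats::runif(n_queries, 0, 5), 1)
    primary <- data.frame(query_id = qid, subject_id = sid,
                          percent_identity = round(identity, 1),
                          alignment_length = as.integer(length_aa),
                          evalue = evalue, bitscore = bitscore,
                          stringsAsFactors = FALSE)
    decoys <- lapply(seq_len(n_queries), function(i) {
      nd <- sample(0:3, 1)
      if (nd == 0) return(NULL)
      data.frame(query_id = qid[i],
                 subject_id = sprintf("REF_%s_d%04d_%d",
                                      sample(families, nd, replace = TRUE),
                                      i, seq_len(nd)),
                 percent_identity = round(stats::runif(nd, 30, 90), 1),
                 alignment_length = as.integer(sample(50:400, nd,
                                                      replace = TRUE)),
                 evalue = 10^(-stats::runif(nd, 2, 11)),
                 bitscore = round(bitscore[i] * stats::runif(nd, 0.3, 0.8),
                                  1),
                 stringsAsFactors = FALSE)
    })
    hits <- rbind(primary, do.call(rbind, decoys))
    hits <- hits[order(hits$query_id, -hits$bitscore), ]
    rownames(hits) <- NULL
    ref_ids <- unique(hits$subject_id)
    reference <- data.frame(
      protein_id = ref_ids,
      family = sub("^REF_([A-Z]+[0-9]+)_.*$", "\\1", ref_ids),
      characterized = stats::runif(length(ref_ids)) < 0.3,
      structure_known = stats::runif(length(ref_ids)) < 0.1,
      stringsAsFactors = FALSE)
    list(hits = hits, reference = reference,
         truth = data.frame(query_id = qid, is_member = is_mem,
                            violation = violation,
                            family = fam, stringsAsFactors = FALSE),
         params = list(n_queries = n_queries,
                       member_fraction = member_fraction, seed = seed))
  })
}

#' Generate a gene tree with planted ancient and recent duplications
#'
#' Builds a rooted species-tagged Newick tree in which
#' `n_ancient` duplication events precede the focal clade's ancestor
#' (each separated lineage retains an outside-clade witness leaf, so the
#' events are datable as ancient) and `n_recent` duplications occur
#' inside the focal species. The focal genes therefore partition into
#' `n_ancient + 1` planted functional subgroups. Because every join of
#' two focal genes is a duplication either before or after the clade
#' ancestor, feasibility requires `n_ancient + n_recent == n_focal - 1`.
#'
#' @param n_focal Number of focal-species genes (>= 1).
#' @param n_ancient Number of duplications predating the clade ancestor.
#' @param n_recent Number of duplications inside the focal species
#'   (default: the value forced by `n_focal` and `n_ancient`).
#' @param n_outside_species Number of outside-clade witness species.
#' @param seed Integer seed.
#' @param focal_species,sister_species Species ids inside the focal
#'   clade.
#' @return List with `newick`, `tree` (a parsed `gene_tree`),
#'   `taxonomy` (a `species_taxonomy`), `partition` (planted list of
#'   gene-id vectors) and `params`.
#' @export
gen_gene_tree <- function(n_focal, n_ancient,
                          n_recent = n_focal - 1 - n_ancient,
                          n_outside_species = 3, seed,
                          focal_species = "Trire2",
                          sister_species = "Fusox1") {
  stopifnot(n_focal >= 1, n_ancient >= 0, n_recent >= 0,
            n_outside_species >= 1)
  if (n_ancient + n_recent != n_focal - 1)
    stop("infeasible parameters: need n_ancient + n_recent == n_focal - 1")
  with_seed(seed, {
    n_parts <- n_ancient + 1
    sizes <- rep(1L, n_parts)
    if (n_recent > 0) {
      extra <- table(factor(sample.int(n_parts, n_recent, replace = TRUE),
                            levels = seq_len(n_parts)))
      sizes <- sizes + as.integer(extra)
    }
    genes <- sprintf("g%03d", seq_len(n_focal))
    genes <- sample(genes)          # random assignment to parts
    parts <- split(genes, rep(seq_len(n_parts), sizes))
    outside <- sprintf("Out%02d", seq_len(n_outside_species))
    caterpillar <- function(leaves) {
      nw <- leaves[1]
      for (k in seq_along(leaves)[-1])
        nw <- paste0("(", nw, ",", leaves[k], ")100")
      nw
    }
    lineage <- function(i) {
      focal_leaves <- paste0(focal_species, "|", parts[[i]])
      part_nw <- caterpillar(focal_leaves)
      part_nw <- paste0("(", part_nw, ",", sister_species, "|s",
                        i, ")100")
      wit <- outside[(i - 1) %% n_outside_species + 1]
      paste0("(", part_nw, ",", wit, "|o", i, ")100")
    }
    nw <- lineage(1)
    if (n_parts > 1)
      for (i in seq(2, n_parts))
        nw <- paste0("(", nw, ",", lineage(i), ")100")
    newick <- paste0(nw, ";")
    tree <- parse_gene_tree(text = newick)
    taxonomy <- species_taxonomy(
      focal_species,
      focal_clade = c(focal_species, sister_species),
      universe = c(focal_species, sister_species, outside))
    list(newick = newick, tree = tree, taxonomy = taxonomy,
         partition = unname(parts),
         params = list(n_focal = n_focal, n_ancient = n_ancient,
                       n_recent = n_recent,
                       n_outside_species = n_outside_species,
                       seed = seed))
  })
}

#' Generate an induction expression dataset with planted effects
#'
#' Emulates the induction experiment's design: every (substrate, time)
#' stratum carries `replicates` biological replicates, substrates are
#' split over two cultivation batches, and each batch has its own
#' time-matched uninduced control series. Baseline log2 signals are drawn
#' per gene from N(8, 1); planted induced genes receive `+effect_lfc` in
#' their designated strata (by default every substrate at every non-zero
#' time point); i.i.d. Gaussian noise with sd `noise_sd` is added on the
#' log2 scale.
#'
#' @param n_genes Number of genes.
#' @param induced_fraction Fraction of genes planted as induced.
#' @param effect_lfc Planted log2 effect size; `0` means no induced genes
#'   (the truth's induced set is empty by convention).
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param substrates Substrate codes (default the ten of the experiment).
#' @param timepoints Sampling times in hours.
#' @param replicates Replicates per stratum (default 4).
#' @param seed Integer seed.
#' @param induced_times Time points at which planted genes are induced
#'   (default all non-zero time points).
#' @return List with `data` (an `expr_dataset`), `truth` (induced gene
#'   ids and their strata) and `params`.
#' @export
gen_expression_dataset <- function(n_genes, induced_fraction = 0.1,
                                   effect_lfc = 2.0, noise_sd = 0.5,
                                   substrates = SUBSTRATES,
                                   timepoints = TIMEPOINTS,
                                   replicates = 4, seed,
                                   induced_times = NULL) {
  stopifnot(n_genes >= 1, induced_fraction >= 0, induced_fraction <= 1,
            noise_sd > 0, replicates >= 2)
  if (is.null(induced_times)) induced_times <- setdiff(timepoints, 0)
  with_seed(seed, {
    batches <- DEFAULT_BATCHES[substrates]
    batches[is.na(batches)] <- 1
    names(batches) <- substrates
    sheet <- list()
    for (sb in substrates)
      for (tp in timepoints)
        sheet[[length(sheet) + 1]] <- data.frame(
          substrate = sb, time_h = tp, replicate = seq_len(replicates),
          batch = unname(batches[sb]), stringsAsFactors = FALSE)
    for (b in unique(batches))
      for (tp in timepoints)
        sheet[[length(sheet) + 1]] <- data.frame(
          substrate = "CONTROL", time_h = tp,
          replicate = seq_len(replicates), batch = b,
          stringsAsFactors = FALSE)
    sheet <- do.call(rbind, sheet)
    sheet$sample_id <- sprintf("%s_t%g_b%d_r%d", sheet$substrate,
                               sheet$time_h, sheet$batch, sheet$replicate)
    genes <- sprintf("gene%04d", seq_len(n_genes))
    n_ind <- if (effect_lfc == 0) 0L else
      round(induced_fraction * n_genes)
    induced <- genes[seq_len(n_ind)]
    baseline <- stats::rnorm(n_genes, 8, 1)
    mat <- matrix(stats::rnorm(n_genes * nrow(sheet), 0, noise_sd),
                  n_genes, nrow(sheet)) + baseline
    dimnames(mat) <- list(genes, sheet$sample_id)
    hot <- sheet$substrate != "CONTROL" & sheet$time_h %in% induced_times
    if (n_ind > 0 && any(hot))
      mat[seq_len(n_ind), hot] <- mat[seq_len(n_ind), hot] + effect_lfc
    strata <- expand.grid(substrate = substrates, time_h = induced_times,
                          stringsAsFactors = FALSE)
    list(data = expr_dataset(mat, sheet),
         truth = list(induced = induced,
                      strata = if (n_ind > 0) strata else strata[0, ],
                      effect_lfc = effect_lfc),
         params = list(n_genes = n_genes,
                       induced_fraction = induced_fraction,
                       effect_lfc = effect_lfc, noise_sd = noise_sd,
                       replicates = replicates, seed = seed))
  })
}
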