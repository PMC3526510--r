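# Orchestration: a run configuration holding the analysis thresholds and
# the two composed pipeline entry points (annotation and expression).

#' Pipeline run configuration
#'
#' Collects every threshold of the analysis with the defaults of the
#' study design: discovery E-value bound 1e-11; confident membership at
#' >= 97% identity over more than 200 aligned amino acids;
#' cluster-acceptance boundary at mean identity 40 over mean length 100;
#' induction calls at p < 0.01 and |log2 fold change| > 0.4; a core set
#' threshold of 70% of the substrates; 18 co-expression branches.
#'
#' @param evalue_max Exclusive E-value bound for the hit filter.
#' @param identity_min,length_min_exclusive Confident-membership bounds.
#' @param cluster_identity_min,cluster_length_min Cluster-acceptance
#'   boundary (mean identity / mean aligned length).
#' @param p_max,lfc_min Induction-call thresholds.
#' @param core_fraction Fraction of substrates for the core induced set.
#' @param n_branches Number of co-expression branches.
#' @param focal_species Focal species id.
#' @param exclude_focal Whether the focal species votes in family
#'   assignment (default: it does not).
#' @param class_map Named vector mapping substrates to
#'   cellulose/xylan/other for the core-set rule.
#' @param seed Integer seed recorded in the run manifest.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(evalue_max = 1e-11, identity_min = 97,
                            length_min_exclusive = 200,
                            cluster_identity_min = 40,
                            cluster_length_min = 100,
                            p_max = 0.01, lfc_min = 0.4,
                            core_fraction = 0.70, n_branches = 18,
                            focal_species = "Trire2",
                            exclude_focal = TRUE,
                            class_map = default_class_map(),
                            seed = 1L) {
  cfg <- list(evalue_max = evalue_max, identity_min = identity_min,
              length_min_exclusive = length_min_exclusive,
              cluster_identity_min = cluster_identity_min,
              cluster_length_min = cluster_length_min,
              p_max = p_max, lfc_min = lfc_min,
              core_fraction = core_fraction, n_branches = n_branches,
              focal_species = focal_species,
              exclude_focal = exclude_focal,
              class_map = class_map, seed = as.integer(seed))
  thr <- c(cfg$evalue_max, cfg$identity_min, cfg$length_min_exclusive,
           cfg$p_max, cfg$lfc_min, cfg$core_fraction, cfg$n_branches)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Default substrate class map for the core-set rule
#'
#' Both Avicel concentrations, spruce and sophorose count as
#' cellulose-class inducers (pretreated spruce is almost pure cellulose
#' and sophorose is the soluble cellulose-derived inducer); the two
#' xylans count as xylan-class; the complex bagasse and wheat-straw
#' materials as other.
#'
#' @return Named character vector over the ten substrate codes.
#' @export
default_class_map <- function() {
  c(AV1 = "cellulose", AV0.75 = "cellulose", SP = "cellulose",
    SO = "cellulose", XO = "xylan", XB = "xylan",
    BO = "other", BS = "other", BE = "other", WH = "other")
}

run_manifest <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(js), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config_md5 = h, seed = config$seed,
       package_version = as.character(utils::packageVersion("lignoCAZy")))
}

#' Run the annotation pipeline
#'
#' Composes membership calling, cluster acceptance, majority-vote family
#' assignment and tree-based subgroup partitioning into one deterministic
#' run over in-memory inputs.
#'
#' @param hits Hit table (see [read_blast_tab()]).
#' @param reference Reference metadata (see [read_reference_tsv()]).
#' @param clusters Cluster membership (see [read_clusters_tsv()]).
#' @param trees Named list of `gene_tree` objects (or Newick strings),
#'   one per cluster id; clusters without a tree get a single subgroup.
#' @param taxonomy A `species_taxonomy`.
#' @param config A `run_config`.
#' @return List with `genes` (per-focal-gene table: gene_id, cluster_id,
#'   family, subgroup, n_subgroups_in_cluster), `clusters` (per-cluster
#'   family calls with acceptance flags), `membership` (per-member
#'   calls) and `manifest`.
#' @export
run_annotate <- function(hits, reference, clusters, trees = list(),
                         taxonomy = NULL, config = pipeline_config()) {
  calls <- membership_calls(hits, queries = unique(clusters$gene_id),
                            evalue_max = config$evalue_max,
                            identity_min = config$identity_min,
                            length_min_exclusive =
                              config$length_min_exclusive)
  fam <- assign_cluster_families(clusters, calls, reference,
                                 focal_species = config$focal_species,
                                 exclude_focal = config$exclude_focal)
  fam$accepted <- vapply(fam$cluster_id, function(cid)
    cluster_acceptance(clusters$gene_id[clusters$cluster_id == cid],
                       calls, config$cluster_identity_min,
                       config$cluster_length_min), TRUE)
  focal <- clusters[clusters$species_id == config$focal_species, ,
                    drop = FALSE]
  gene_rows <- lapply(unique(focal$cluster_id), function(cid) {
    genes <- focal$gene_id[focal$cluster_id == cid]
    tr <- trees[[cid]]
    if (!is.null(tr)) {
      if (is.character(tr)) tr <- parse_gene_tree(text = tr)
      sg <- subgroup_table(tr, taxonomy, cid)
      sg <- sg[match(genes, sg$gene_id), , drop = FALSE]
      sub <- sg$subgroup_label
      nsub <- sg$n_subgroups_in_cluster
    } else {
      sub <- rep(paste0(cid, "a"), length(genes))
      nsub <- rep(1L, length(genes))
    }
    data.frame(gene_id = genes, cluster_id = cid,
               family = fam$family[fam$cluster_id == cid],
               accepted = fam$accepted[fam$cluster_id == cid],
               subgroup = sub, n_subgroups_in_cluster = nsub,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_rows)
  list(genes = genes, clusters = fam, membership = calls,
       manifest = run_manifest(config))
}

#' Run the expression-induction pipeline
#'
#' Computes every induced-vs-control contrast, the induction calls, the
#' induced and core induced gene sets, the per-gene maximal-induction
#' profile, the co-expression branches of the fold-change matrix and,
#' when an annotation is supplied, the family-by-substrate induction
#' count matrix.
#'
#' @param data An `expr_dataset`.
#' @param config A `run_config`.
#' @param annotation Optional gene-to-family map (named vector or
#'   annotation table).
#' @return List with `contrasts`, `induced`, `core`, `max_profile`,
#'   `branches`, `family_matrix` (or `NULL`) and `manifest`.
#' @export
run_express <- function(data, config = pipeline_config(),
                        annotation = NULL) {
  if (!"CONTROL" %in% data$samples$substrate)
    stop("no CONTROL samples in the dataset")
  ct <- contrast_table(data, p_max = config$p_max,
                       lfc_min = config$lfc_min)
  lfc_mat <- lfc_profile_matrix(ct)
  k <- min(config$n_branches, nrow(lfc_mat))
  list(contrasts = ct,
       induced = induced_gene_set(ct),
       core = core_induced_set(ct, config$class_map,
                               config$core_fraction),
       max_profile = max_induction_profile(ct),
       branches = cluster_coexpression_branches(lfc_mat, k = k),
       family_matrix = if (!is.null(annotation))
         family_induction_matrix(ct, annotation) else NULL,
       manifest = run_manifest(config))
}

#' Fold-change profile matrix from a contrast table
#'
#' Genes in rows, (substrate, time) conditions in columns, in the order
#' the contrasts appear.
#'
#' @param calls A `contrast_table`.
#' @return Numeric matrix.
#' @export
lfc_profile_matrix <- function(calls) {
  key <- paste(calls$substrate, calls$time_h, sep = "_")
  cols <- unique(key)
  genes <- unique(calls$gene_id)
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(calls$gene_id, key)] <- calls$lfc
  m
}
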