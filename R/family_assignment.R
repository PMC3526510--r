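# Homology-hit filtering, CAZyme membership calls and majority-vote family
# assignment for protein homology clusters.

CAZY_CLASSES <- c("GH", "CE", "PL", "GT", "CBM")

#' Validate a CAZy family label
#'
#' A fully specified family label is one of the five CAZy class prefixes
#' (GH, CE, PL, GT, CBM) followed by a positive integer, e.g. `"GH3"`.
#'
#' @param x Character vector of candidate labels.
#' @return Logical vector, `TRUE` where the label is well formed.
#' @export
is_cazy_family <- function(x) {
  grepl(paste0("^(", paste(CAZY_CLASSES, collapse = "|"), ")[0-9]+$"), x)
}

#' Read a BLAST tabular hit file
#'
#' Reads the 12-column tabular format (`outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), tab-separated, no header. Extra trailing columns are
#' tolerated and dropped.
#'
#' @param path Path to the hit file.
#' @return A data frame of hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 12)
    stop("expected at least 12 tab-separated columns in ", path)
  hits <- data.frame(
    query_id         = as.character(raw[[1]]),
    subject_id       = as.character(raw[[2]]),
    percent_identity = as.numeric(raw[[3]]),
    alignment_length = as.integer(raw[[4]]),
    evalue           = as.numeric(raw[[11]]),
    bitscore         = as.numeric(raw[[12]]),
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  hits
}

#' Write hits in BLAST tabular form
#'
#' Inverse of [read_blast_tab()]; filler columns (mismatch, gapopen and
#' coordinates) are written as zeros.
#'
#' @param hits Hit data frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    hits$percent_identity, hits$alignment_length,
                    0L, 0L, 0L, 0L, 0L, 0L,
                    format(hits$evalue, scientific = TRUE, trim = TRUE),
                    hits$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  need <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
    stop("percent_identity outside [0, 100]")
  if (any(hits$alignment_length < 1))
    stop("alignment_length must be >= 1")
  if (any(hits$evalue < 0))
    stop("evalue must be non-negative")
  invisible(hits)
}

#' Read CAZy reference metadata
#'
#' TSV with header `protein_id`, `family`, `characterized` (0/1),
#' `structure_known` (0/1). A protein present in several CAZy families
#' occupies one row per family.
#'
#' @param path Path to the TSV file.
#' @return Data frame with logical `characterized` and `structure_known`.
#' @export
read_reference_tsv <- function(path) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("protein_id", "family", "characterized", "structure_known")
  miss <- setdiff(need, names(ref))
  if (length(miss))
    stop("reference table lacks columns: ", paste(miss, collapse = ", "))
  bad <- !is_cazy_family(ref$family)
  if (any(bad))
    stop("malformed CAZy family label(s): ",
         paste(unique(ref$family[bad]), collapse = ", "))
  ref$characterized <- as.logical(as.integer(ref$characterized))
  ref$structure_known <- as.logical(as.integer(ref$structure_known))
  ref
}

#' Read homology-cluster membership
#'
#' TSV with header `gene_id`, `species_id`, `cluster_id`: one row per
#' member of each protein homology cluster across the species panel.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three columns above.
#' @export
read_clusters_tsv <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("gene_id", "species_id", "cluster_id")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("cluster table lacks columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(cl[c("cluster_id", "gene_id")])
  if (any(dup))
    stop("duplicate gene within a cluster: ",
         paste(cl$gene_id[dup][1], cl$cluster_id[dup][1]))
  cl
}

#' Filter hits by E-value
#'
#' Retains only hits with E-value strictly below the threshold, preserving
#' input order. The default reproduces the discovery filter of keeping
#' matches with E-value smaller than 1e-11.
#'
#' @param hits Hit data frame (see [read_blast_tab()]).
#' @param max_exclusive Exclusive upper bound on the E-value.
#' @return The retained rows of `hits`.
#' @export
filter_hits_by_evalue <- function(hits, max_exclusive = 1e-11) {
  if (!is.numeric(max_exclusive) || length(max_exclusive) != 1 ||
      is.na(max_exclusive) || max_exclusive < 0)
    stop("max_exclusive must be a single non-negative number")
  validate_hits(hits)
  hits[hits$evalue < max_exclusive, , drop = FALSE]
}

#' Best hit for one query
#'
#' Selects the hit with the maximal bitscore among hits of a single query.
#' Ties are broken by lower E-value, then by lexicographically smallest
#' subject id, so the choice is deterministic.
#'
#' @param hits Hit data frame; all rows must share one `query_id`.
#' @return A one-row data frame, or `NULL` for empty input.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  validate_hits(hits)
  if (length(unique(hits$query_id)) > 1)
    stop("best_hit expects hits of a single query; got: ",
         paste(unique(hits$query_id), collapse = ", "))
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  hits[ord[1], , drop = FALSE]
}

#' Best characterized hit for one query
#'
#' [best_hit()] restricted to subjects flagged as biochemically
#' characterized in the reference metadata.
#'
#' @param hits Hit data frame for a single query.
#' @param reference Reference data frame (see [read_reference_tsv()]).
#' @return A one-row data frame, or `NULL` if no characterized subject
#'   was hit.
#' @export
best_characterized_hit <- function(hits, reference) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  validate_hits(hits)
  unknown <- setdiff(hits$subject_id, reference$protein_id)
  if (length(unknown))
    stop("subject id(s) missing from reference: ",
         paste(unknown, collapse = ", "))
  chr <- unique(reference$protein_id[reference$characterized])
  sub <- hits[hits$subject_id %in% chr, , drop = FALSE]
  best_hit(sub)
}

#' Confident CAZyme membership from a single hit
#'
#' A protein is a confident CAZyme member if its best reference hit has at
#' least 97% identity covering more than 200 aligned amino acids. Both the
#' inclusive identity bound and the exclusive length bound are exposed.
#'
#' @param hit One-row hit data frame, or a hit table (vectorized).
#' @param identity_min Inclusive lower bound on percent identity.
#' @param length_min_exclusive Exclusive lower bound on alignment length.
#' @return Logical vector, one value per row of `hit`.
#' @export
is_confident_member <- function(hit, identity_min = 97,
                                length_min_exclusive = 200) {
  if (is.null(hit) || nrow(hit) == 0) return(logical(0))
  validate_hits(hit)
  hit$percent_identity >= identity_min &
    hit$alignment_length > length_min_exclusive
}

#' Membership calls for a set of queries
#'
#' Applies the E-value filter, picks each query's best hit and applies the
#' identity/length membership rule. Queries whose hits are all filtered
#' out are returned with `is_cazyme = FALSE` and no supporting hit.
#'
#' @param hits Hit data frame for any number of queries.
#' @param queries Optional character vector of query ids to report on
#'   (defaults to the queries present in `hits`).
#' @param evalue_max Exclusive E-value bound passed to
#'   [filter_hits_by_evalue()].
#' @param identity_min,length_min_exclusive Membership rule bounds, see
#'   [is_confident_member()].
#' @return Data frame with columns `protein_id`, `is_cazyme`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `evalue`,
#'   `bitscore` (supporting-hit fields are `NA` when no hit survived).
#' @export
membership_calls <- function(hits, queries = NULL, evalue_max = 1e-11,
                             identity_min = 97, length_min_exclusive = 200) {
  kept <- filter_hits_by_evalue(hits, evalue_max)
  if (is.null(queries)) queries <- unique(hits$query_id)
  rows <- lapply(queries, function(q) {
    bh <- best_hit(kept[kept$query_id == q, , drop = FALSE])
    if (is.null(bh)) {
      data.frame(protein_id = q, is_cazyme = FALSE, subject_id = NA_character_,
                 percent_identity = NA_real_, alignment_length = NA_integer_,
                 evalue = NA_real_, bitscore = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = q,
                 is_cazyme = is_confident_member(bh, identity_min,
                                                 length_min_exclusive),
                 subject_id = bh$subject_id,
                 percent_identity = bh$percent_identity,
                 alignment_length = bh$alignment_length,
                 evalue = bh$evalue, bitscore = bh$bitscore,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Cluster-level acceptance from mean hit quality
#'
#' A homology cluster is accepted when the mean percent identity and the
#' mean alignment length of its members' best hits both meet a rectangular
#' boundary. Members without a hit are ignored in the means; a cluster
#' with no hits at all is rejected.
#'
#' @param members Character vector of member gene ids.
#' @param best_hits Data frame of per-member best hits with columns
#'   `protein_id`, `percent_identity`, `alignment_length` (members may be
#'   absent).
#' @param identity_min Minimal mean percent identity (default 40).
#' @param length_min Minimal mean alignment length (default 100).
#' @return Single logical.
#' @export
cluster_acceptance <- function(members, best_hits, identity_min = 40,
                               length_min = 100) {
  hb <- best_hits[best_hits$protein_id %in% members &
                    !is.na(best_hits$percent_identity), , drop = FALSE]
  if (nrow(hb) == 0) return(FALSE)
  mean(hb$percent_identity) >= identity_min &&
    mean(hb$alignment_length) >= length_min
}

#' Majority-vote CAZy family for a cluster
#'
#' Each cluster member with a family-labelled hit casts one vote per
#' family it supports (a member whose reference protein sits in several
#' CAZy families gives each family a full vote). The modal family wins;
#' ties are broken by the larger summed bitscore of the supporting
#' members, then by the lexicographically smallest family label. With no
#' voting members the cluster is `"UNASSIGNED"`.
#'
#' @param votes Data frame with columns `gene_id`, `family` and optionally
#'   `bitscore` (used only for tie-breaking; defaults to 0).
#' @param cluster_id Cluster identifier carried through to the result.
#' @return A list of class `family_call` with elements `cluster_id`,
#'   `family`, `tally` (named integer vector) and `tie_broken`.
#' @export
majority_vote_family <- function(votes, cluster_id = NA_character_) {
  if (is.null(votes) || nrow(votes) == 0 || all(is.na(votes$family))) {
    call <- list(cluster_id = cluster_id, family = "UNASSIGNED",
                 tally = integer(0), tie_broken = FALSE)
    class(call) <- "family_call"
    return(call)
  }
  v <- votes[!is.na(votes$family), , drop = FALSE]
  if (is.null(v$bitscore)) v$bitscore <- 0
  tally <- table(v$family)
  tally <- sort(tally, decreasing = TRUE)
  top <- names(tally)[tally == max(tally)]
  tie <- length(top) > 1
  if (tie) {
    wt <- vapply(top, function(f) sum(v$bitscore[v$family == f]), 0)
    top <- top[wt == max(wt)]
    top <- sort(top)[1]
  }
  call <- list(cluster_id = cluster_id, family = top[1],
               tally = stats::setNames(as.integer(tally), names(tally)),
               tie_broken = tie)
  class(call) <- "family_call"
  call
}

#' @export
print.family_call <- function(x, ...) {
  cat("cluster", x$cluster_id, "->", x$family,
      if (x$tie_broken) "(tie broken)" else "", "\n")
  invisible(x)
}

#' Assign a CAZy family to every cluster
#'
#' Combines membership calls, the reference family labels and the cluster
#' membership into one majority-vote family call per cluster. By default
#' the focal species' own genes do not vote, so that the assignment rests
#' on the family membership of the other species in the panel.
#'
#' @param clusters Cluster membership data frame (see
#'   [read_clusters_tsv()]).
#' @param calls Membership calls from [membership_calls()] for the cluster
#'   members (gene ids in `protein_id`).
#' @param reference Reference metadata (see [read_reference_tsv()]).
#' @param focal_species Species id whose genes are excluded from voting
#'   when `exclude_focal` is `TRUE`; use `NULL` to let every member vote.
#' @param exclude_focal Whether the focal species' genes are excluded from
#'   the vote (default `TRUE`).
#' @return Data frame with one row per cluster: `cluster_id`, `family`,
#'   `n_votes`, `tie_broken`.
#' @export
assign_cluster_families <- function(clusters, calls, reference,
                                    focal_species = NULL,
                                    exclude_focal = TRUE) {
  fam_of <- split(reference$family, reference$protein_id)
  ids <- unique(clusters$cluster_id)
  rows <- lapply(ids, function(cid) {
    mem <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    if (exclude_focal && !is.null(focal_species))
      mem <- mem[mem$species_id != focal_species, , drop = FALSE]
    mc <- calls[calls$protein_id %in% mem$gene_id & calls$is_cazyme, ,
                drop = FALSE]
    votes <- do.call(rbind, lapply(seq_len(nrow(mc)), function(i) {
      fams <- fam_of[[mc$subject_id[i]]]
      if (is.null(fams)) return(NULL)
      data.frame(gene_id = mc$protein_id[i], family = fams,
                 bitscore = mc$bitscore[i], stringsAsFactors = FALSE)
    }))
    fc <- majority_vote_family(votes, cluster_id = cid)
    data.frame(cluster_id = cid, family = fc$family,
               n_votes = sum(fc$tally), tie_broken = fc$tie_broken,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
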