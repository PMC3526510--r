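# Parsing, validation and summary counts for the curated CAZyme
# annotation table (gene id, name, family, annotation text, CBM,
# provenance, homology cluster, functional subgroup).

ANNOT_COLS <- c("gene_id", "name", "family", "annotation", "cbm", "ref",
                "cluster", "subgroup")

#' Path to the bundled annotation-table fixture
#'
#' The curated CAZyme annotation table of the *Trichoderma reesei*
#' genome (glycoside hydrolase, carbohydrate esterase and polysaccharide
#' lyase genes, excluding GT and CE10), shipped as a UTF-8 TSV.
#'
#' @return File path.
#' @export
annotation_fixture_path <- function() {
  system.file("extdata", "treesei_cazyme_annotation.tsv",
              package = "lignoCAZy", mustWork = TRUE)
}

#' Parse a curated annotation table
#'
#' TSV with header `gene_id`, `name`, `family`, `annotation`, `cbm`,
#' `ref`, `cluster`, `subgroup`. Empty cells become `NA`. Validation:
#' the family class prefix must be GH, CE or PL (a bare class label such
#' as `"GH"` marks a gene whose family could not be assigned), and a
#' subgroup label must start with the row's cluster id. A subgroup equal
#' to the bare cluster id (no letter suffix) is accepted with a warning.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `annotation_table`.
#' @export
parse_annotation_table <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                            colClasses = "character",
                            encoding = "UTF-8")
  miss <- setdiff(ANNOT_COLS, names(rows))
  if (length(miss))
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  for (cc in ANNOT_COLS) {
    rows[[cc]] <- trimws(rows[[cc]])
    rows[[cc]][rows[[cc]] == ""] <- NA_character_
  }
  bad <- !grepl("^(GH|CE|PL)[0-9]*$", rows$family)
  if (any(bad))
    stop("unknown family class in row(s): ",
         paste(rows$gene_id[bad], collapse = ", "))
  has_sub <- !is.na(rows$subgroup) & !is.na(rows$cluster)
  pref <- startsWith(rows$subgroup[has_sub], rows$cluster[has_sub])
  if (any(!pref))
    stop("subgroup does not start with cluster id in row(s): ",
         paste(rows$gene_id[has_sub][!pref], collapse = ", "))
  letterless <- has_sub & !is.na(rows$subgroup) &
    rows$subgroup == rows$cluster
  if (any(letterless))
    warning("subgroup label(s) without letter suffix: ",
            paste(rows$gene_id[letterless], collapse = ", "))
  class(rows) <- c("annotation_table", class(rows))
  rows
}

#' Write an annotation table to TSV
#'
#' Inverse of [parse_annotation_table()]; `NA` cells are written empty.
#'
#' @param rows An `annotation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(rows, path) {
  out <- as.data.frame(rows)[ANNOT_COLS]
  for (cc in ANNOT_COLS) out[[cc]][is.na(out[[cc]])] <- ""
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

family_class <- function(family) sub("[0-9]+$", "", family)

#' Gene counts per CAZy class
#'
#' @param rows An `annotation_table`.
#' @return List with `counts` (named integer vector per class) and
#'   `total` (number of rows).
#' @export
count_by_class <- function(rows) {
  cls <- family_class(rows$family)
  counts <- table(factor(cls, levels = c("GH", "CE", "PL")))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total = nrow(rows))
}

#' Number of distinct fully-specified CAZy families
#'
#' Bare class labels (family `"GH"` with no number, i.e. unassigned
#' genes) are excluded.
#'
#' @param rows An `annotation_table`.
#' @return Integer.
#' @export
count_distinct_families <- function(rows) {
  full <- grepl("^(GH|CE|PL)[0-9]+$", rows$family)
  length(unique(rows$family[full]))
}

#' Families split over more than one homology cluster
#'
#' @param rows An `annotation_table`.
#' @return List with `n_multicluster` (families with >= 2 distinct
#'   clusters) and `clusters_per_family` (named integer vector).
#' @export
count_multicluster_families <- function(rows) {
  full <- grepl("^(GH|CE|PL)[0-9]+$", rows$family) & !is.na(rows$cluster)
  per <- tapply(rows$cluster[full], rows$family[full],
                function(x) length(unique(x)))
  per <- stats::setNames(as.integer(per), names(per))
  list(n_multicluster = sum(per >= 2L), clusters_per_family = per)
}

ref_tokens <- function(ref) {
  if (is.na(ref)) return(character(0))
  trimws(strsplit(ref, ",", fixed = TRUE)[[1]])
}

#' Provenance counts: newly identified and refined annotations
#'
#' A row whose provenance is the literal `This study` is a newly
#' identified gene; a row carrying the standalone update token `A` had a
#' previous annotation refined or replaced. The two are disjoint by
#' construction.
#'
#' @param rows An `annotation_table`.
#' @return List with `new` and `refined` integer counts.
#' @export
count_provenance <- function(rows) {
  toks <- lapply(rows$ref, ref_tokens)
  new <- vapply(toks, function(t) length(t) > 0 && all(t == "This study"),
                TRUE)
  refined <- vapply(toks, function(t) "A" %in% t, TRUE)
  list(new = sum(new), refined = sum(refined & !new))
}

#' Rows whose annotation contains a keyword
#'
#' Case-insensitive Unicode-aware substring match after NFC
#' normalization, so e.g. a beta ligature matches regardless of the
#' composition form the table was typed in. Optionally restricted to one
#' family.
#'
#' @param rows An `annotation_table`.
#' @param keyword Substring to search for in the annotation text.
#' @param family Family label to restrict to, or `NULL` for any family.
#' @return The matching rows.
#' @export
match_keyword <- function(rows, keyword, family = NULL) {
  ann <- stringi::stri_trans_nfc(rows$annotation)
  key <- stringi::stri_trans_nfc(keyword)
  hit <- !is.na(ann) &
    stringi::stri_detect_fixed(ann, key, case_insensitive = TRUE)
  if (!is.null(family)) hit <- hit & rows$family == family
  rows[hit, , drop = FALSE]
}

#' Count rows whose annotation contains a keyword
#'
#' @inheritParams match_keyword
#' @return Integer count.
#' @export
count_keyword <- function(rows, keyword, family = NULL) {
  nrow(match_keyword(rows, keyword, family))
}

#' Genes sharing a homology cluster
#'
#' @param rows An `annotation_table`.
#' @param cluster_id Cluster to look up; alternatively give `gene` or
#'   `name` to look the cluster up from a member.
#' @param gene,name Optional member gene id / gene name.
#' @return The rows of the cluster.
#' @export
genes_in_cluster <- function(rows, cluster_id = NULL, gene = NULL,
                             name = NULL) {
  if (is.null(cluster_id)) {
    if (!is.null(gene)) cluster_id <- rows$cluster[rows$gene_id == gene]
    else if (!is.null(name)) cluster_id <- rows$cluster[!is.na(rows$name) &
                                                          rows$name == name]
    else stop("give cluster_id, gene or name")
    cluster_id <- unique(cluster_id[!is.na(cluster_id)])
    if (length(cluster_id) != 1)
      stop("could not resolve a unique cluster")
  }
  rows[!is.na(rows$cluster) & rows$cluster == cluster_id, , drop = FALSE]
}

#' Full summary of an annotation table
#'
#' All headline counts in one list: per-class gene counts, total,
#' distinct families, multi-cluster families and provenance counts.
#'
#' @param rows An `annotation_table`.
#' @return Named list of counts.
#' @export
summarize_annotation <- function(rows) {
  cls <- count_by_class(rows)
  mc <- count_multicluster_families(rows)
  prov <- count_provenance(rows)
  list(gh_genes = cls$counts[["GH"]],
       ce_genes = cls$counts[["CE"]],
       pl_genes = cls$counts[["PL"]],
       total_genes = cls$total,
       distinct_families = count_distinct_families(rows),
       multicluster_families = mc$n_multicluster,
       new_genes = prov$new,
       refined_annotations = prov$refined)
}

#' Write an annotation summary as JSON
#'
#' @param rows An `annotation_table`.
#' @param path Output path.
#' @return The summary list, invisibly.
#' @export
write_annotation_summary <- function(rows, path) {
  s <- summarize_annotation(rows)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
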