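# Species-overlap duplication detection in species-tagged gene trees and
# partitioning of focal-species paralogues into functional subgroups.

#' Species taxonomy for duplication dating
#'
#' Bundles the focal species (the annotated genome), the focal clade it
#' belongs to, and the universe of species that may appear in gene trees.
#'
#' @param focal_species Single species id, e.g. `"Trire2"`.
#' @param focal_clade Character vector of species ids forming the focal
#'   clade (must contain `focal_species`).
#' @param universe Character vector of all admissible species ids
#'   (defaults to `focal_clade`, i.e. no outside species known).
#' @return A list of class `species_taxonomy`.
#' @export
species_taxonomy <- function(focal_species, focal_clade,
                             universe = focal_clade) {
  if (!focal_species %in% focal_clade)
    stop("focal_species must be a member of focal_clade")
  if (!all(focal_clade %in% universe))
    stop("focal_clade must be contained in the species universe")
  structure(list(focal_species = focal_species,
                 focal_clade = unique(focal_clade),
                 universe = unique(universe)),
            class = "species_taxonomy")
}

#' Read a species taxonomy from TSV
#'
#' TSV with header `species_id`, `in_focal_clade` (0/1); the focal species
#' is named separately.
#'
#' @param path Path to the TSV file.
#' @param focal_species Species id of the focal (annotated) genome.
#' @return A `species_taxonomy` object.
#' @export
read_taxonomy <- function(path, focal_species) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("species_id", "in_focal_clade")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("taxonomy table lacks columns: ", paste(miss, collapse = ", "))
  species_taxonomy(focal_species,
                   focal_clade = tx$species_id[tx$in_focal_clade == 1],
                   universe = tx$species_id)
}

#' Parse a species-tagged gene tree from Newick
#'
#' Leaf labels are `SPECIES<delimiter>GENE`. Numeric internal-node labels
#' are interpreted as support values. An unrooted trifurcating tree is
#' accepted and treated as rooted at the trifurcation. A bare single-leaf
#' tree (`"A|g1;"`) is also accepted.
#'
#' @param text Newick string (use either `text` or `file`).
#' @param file Path to a Newick file containing one tree.
#' @param delimiter Separator between species and gene in leaf labels.
#' @return A list of class `gene_tree` with elements `phylo` (an
#'   [ape::read.tree()] tree, or `NULL` for a single leaf), `species`,
#'   `gene` (per-leaf, in leaf order) and `delimiter`.
#' @export
parse_gene_tree <- function(text = NULL, file = NULL, delimiter = "|") {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  if (!grepl("\\(", text)) {
    # degenerate single-leaf tree: "label;"
    lab <- sub(";\\s*$", "", text)
    sg <- split_leaf_labels(lab, delimiter)
    gt <- list(phylo = NULL, species = sg$species, gene = sg$gene,
               leaf_label = lab, delimiter = delimiter)
    class(gt) <- "gene_tree"
    return(gt)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick: could not parse input")
  sg <- split_leaf_labels(phy$tip.label, delimiter)
  key <- paste(sg$species, sg$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate leaf: ", phy$tip.label[duplicated(key)][1])
  gt <- list(phylo = phy, species = sg$species, gene = sg$gene,
             leaf_label = phy$tip.label, delimiter = delimiter)
  class(gt) <- "gene_tree"
  gt
}

split_leaf_labels <- function(labels, delimiter) {
  hit <- grepl(delimiter, labels, fixed = TRUE)
  if (!all(hit))
    stop("leaf label without '", delimiter, "' delimiter: ",
         labels[!hit][1])
  pos <- regexpr(delimiter, labels, fixed = TRUE)
  list(species = substr(labels, 1, pos - 1),
       gene = substr(labels, pos + nchar(delimiter), nchar(labels)))
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree with", length(x$gene), "leaves,",
      length(unique(x$species)), "species\n")
  invisible(x)
}

n_leaves <- function(gt) length(gt$gene)

# per-node descendant tip indices (postorder accumulation); nodes are ape
# numbers: tips 1..n, internals n+1..n+Nnode
node_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

node_support <- function(phy) {
  n <- length(phy$tip.label)
  sup <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    num <- suppressWarnings(as.numeric(phy$node.label))
    sup[seq_along(num)] <- num
  }
  stats::setNames(sup, n + seq_len(phy$Nnode))
}

#' Detect gene duplications by species overlap
#'
#' An internal node is called a duplication when at least two of its child
#' subtrees contain overlapping species sets. Events are reported in
#' preorder (root first) with the node's full descendant species set and
#' its support value, if one was parsed.
#'
#' @param gt A `gene_tree` from [parse_gene_tree()].
#' @return Data frame with columns `node` (ape node number), `support`,
#'   and a list-column `species_set`; zero rows when there is no
#'   duplication.
#' @export
detect_duplications <- function(gt) {
  empty <- data.frame(node = integer(0), support = numeric(0))
  empty$species_set <- list()
  if (is.null(gt$phylo)) return(empty)
  phy <- gt$phylo
  n <- length(phy$tip.label)
  sets <- node_tip_sets(phy)
  sup <- node_support(phy)
  # preorder over internal nodes: order of first appearance as a parent
  # in the cladewise edge matrix (root first)
  pre <- unique(ape::reorder.phylo(phy, "cladewise")$edge[, 1])
  rows <- list()
  for (nd in pre) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    ksp <- lapply(kids, function(k) unique(gt$species[sets[[k]]]))
    dup <- FALSE
    if (length(ksp) >= 2) {
      for (i in seq_len(length(ksp) - 1)) {
        for (j in seq(i + 1, length(ksp))) {
          if (length(intersect(ksp[[i]], ksp[[j]]))) { dup <- TRUE; break }
        }
        if (dup) break
      }
    }
    if (dup) {
      r <- data.frame(node = nd, support = unname(sup[as.character(nd)]))
      r$species_set <- list(unique(gt$species[sets[[nd]]]))
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Is a duplication ancient relative to the focal clade?
#'
#' A duplication predates the focal clade's common ancestor when its
#' descendant species set extends outside the clade (the node maps above
#' the clade root in the species taxonomy). Such ancient duplications are
#' the signal of functional diversification between the focal paralogues.
#'
#' @param species_set Character vector of species under the duplication
#'   node (or a one-row slice of the [detect_duplications()] output).
#' @param taxonomy A `species_taxonomy`.
#' @return Single logical.
#' @export
is_ancient <- function(species_set, taxonomy) {
  if (is.data.frame(species_set)) species_set <- species_set$species_set[[1]]
  if (!length(species_set)) stop("empty species set")
  unknown <- setdiff(species_set, taxonomy$universe)
  if (length(unknown))
    stop("species not in taxonomy: ", paste(unknown, collapse = ", "))
  !all(species_set %in% taxonomy$focal_clade)
}

#' Partition focal-species genes into functional subgroups
#'
#' Two focal genes fall in the same subgroup exactly when the species set
#' under their lowest common ancestor lies entirely inside the focal
#' clade, i.e. no duplication predating the clade's ancestor separates
#' them. The relation is an equivalence on the tree, so the result is a
#' partition.
#'
#' @param gt A `gene_tree`.
#' @param taxonomy A `species_taxonomy`.
#' @return A list of character vectors of focal gene ids (the parts);
#'   empty list when the tree has no focal leaves.
#' @export
partition_focal_subgroups <- function(gt, taxonomy) {
  focal <- which(gt$species == taxonomy$focal_species)
  unknown <- setdiff(unique(gt$species), taxonomy$universe)
  if (length(unknown))
    stop("species not in taxonomy: ", paste(unknown, collapse = ", "))
  if (!length(focal)) return(list())
  if (length(focal) == 1 || is.null(gt$phylo))
    return(list(gt$gene[focal]))
  phy <- gt$phylo
  sets <- node_tip_sets(phy)
  inside <- vapply(sets, function(tips)
    all(gt$species[tips] %in% taxonomy$focal_clade), TRUE)
  m <- ape::mrca(phy)
  # union-find over focal tips
  parent <- seq_along(focal)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(length(focal) - 1)) {
    for (b in seq(a + 1, length(focal))) {
      anc <- m[focal[a], focal[b]]
      if (inside[anc]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(focal), find, 1L)
  unname(lapply(split(gt$gene[focal], roots), as.character))
}

subgroup_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  # extend a..z with aa, ab, ...
  extra <- n - 26
  two <- as.vector(t(outer(letters, letters, paste0)))
  c(letters, two[seq_len(extra)])
}

#' Label subgroup parts with cluster-id + letter
#'
#' Parts are ordered by the first appearance of any member in
#' left-to-right leaf order and receive suffixes `a`, `b`, `c`, ...
#' (extended to `aa`, `ab`, ... past 26), prefixed with the cluster id,
#' e.g. `"110e"`.
#'
#' @param partition List of character vectors of focal gene ids, as from
#'   [partition_focal_subgroups()].
#' @param cluster_id Homology-cluster identifier used as the prefix.
#' @param gt The `gene_tree` the partition came from (defines leaf order).
#' @return Named character vector mapping gene id to subgroup label.
#' @export
label_subgroups <- function(partition, cluster_id, gt) {
  if (!length(partition)) return(stats::setNames(character(0), character(0)))
  if (any(!vapply(partition, length, 1L)))
    stop("empty part in partition")
  first_pos <- vapply(partition, function(p)
    min(match(p, gt$gene)), 1)
  ord <- order(first_pos)
  suff <- subgroup_letters(length(partition))
  out <- character(0)
  for (k in seq_along(ord)) {
    p <- partition[[ord[k]]]
    out[p] <- paste0(cluster_id, suff[k])
  }
  out
}

#' Subgroup table for one cluster's gene tree
#'
#' Convenience wrapper: partitions the focal genes of a tree and labels
#' the parts, returning the per-gene output table.
#'
#' @param gt A `gene_tree`.
#' @param taxonomy A `species_taxonomy`.
#' @param cluster_id Cluster identifier (label prefix).
#' @return Data frame with columns `gene_id`, `cluster_id`,
#'   `subgroup_label`, `n_subgroups_in_cluster`.
#' @export
subgroup_table <- function(gt, taxonomy, cluster_id) {
  part <- partition_focal_subgroups(gt, taxonomy)
  labs <- label_subgroups(part, cluster_id, gt)
  if (!length(labs))
    return(data.frame(gene_id = character(0), cluster_id = character(0),
                      subgroup_label = character(0),
                      n_subgroups_in_cluster = integer(0)))
  data.frame(gene_id = names(labs), cluster_id = cluster_id,
             subgroup_label = unname(labs),
             n_subgroups_in_cluster = length(part),
             stringsAsFactors = FALSE)
}
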