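# Independent oracles and fixture builders shared across tests.

# brute-force species-overlap duplication check using phangorn's
# descendant enumeration (independent of the package's traversal)
brute_force_duplications <- function(gt) {
  phy <- gt$phylo
  if (is.null(phy)) return(integer(0))
  n <- length(phy$tip.label)
  internal <- (n + 1):(n + phy$Nnode)
  dup <- integer(0)
  for (nd in internal) {
    kids <- phangorn::Descendants(phy, nd, type = "children")
    sp <- lapply(kids, function(k) {
      tips <- if (k <= n) k else unlist(phangorn::Descendants(phy, k, "tips"))
      unique(gt$species[tips])
    })
    overlap <- FALSE
    if (length(sp) >= 2) {
      for (i in seq_len(length(sp) - 1))
        for (j in seq(i + 1, length(sp)))
          if (length(intersect(sp[[i]], sp[[j]]))) overlap <- TRUE
    }
    if (overlap) dup <- c(dup, nd)
  }
  dup
}

# random species-tagged gene tree on a species panel
rand_gene_tree <- function(n_leaves, species_pool, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_leaves)
  sp <- sample(species_pool, n_leaves, replace = TRUE)
  phy$tip.label <- paste0(sp, "|g", seq_len(n_leaves))
  parse_gene_tree(text = ape::write.tree(phy))
}

# canonical form of a partition (order-free comparison)
canon_partition <- function(parts) {
  unname(sort(vapply(parts, function(p)
    paste(sort(as.character(p)), collapse = ","), "")))
}

# brute-force subgroup relation: pairwise LCA species sets closed under
# transitivity via repeated relational closure on the adjacency matrix
brute_force_partition <- function(gt, taxonomy) {
  focal <- which(gt$species == taxonomy$focal_species)
  if (!length(focal)) return(list())
  if (length(focal) == 1 || is.null(gt$phylo))
    return(list(gt$gene[focal]))
  phy <- gt$phylo
  n <- length(phy$tip.label)
  adj <- diag(length(focal)) > 0
  for (a in seq_along(focal))
    for (b in seq_along(focal)) {
      if (a == b) next
      anc <- ape::getMRCA(phy, c(focal[a], focal[b]))
      tips <- unlist(phangorn::Descendants(phy, anc, "tips"))
      adj[a, b] <- all(gt$species[tips] %in% taxonomy$focal_clade)
    }
  # transitive closure
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, length(focal))
  cid <- 0
  for (i in seq_along(focal)) {
    if (is.na(comp[i])) { cid <- cid + 1; comp[which(adj[i, ])] <- cid }
  }
  unname(lapply(split(gt$gene[focal], comp), as.character))
}

# bundle a hit table, cluster membership, gene trees and taxonomy with a
# consistent ground truth, for end-to-end annotation runs
gen_annotation_bundle <- function(n_clusters = 4, members_per_cluster = 5,
                                  focal_per_cluster = 3, seed = 1) {
  ht <- gen_hit_table(n_clusters * members_per_cluster, 1, seed = seed)
  set.seed(seed + 1000)
  fams <- unique(ht$truth$family)
  # one cluster per family actually present, cycling if fewer families
  cl_fam <- rep(fams, length.out = n_clusters)
  qs <- split(ht$truth$query_id,
              rep(seq_len(n_clusters), each = members_per_cluster))
  # reassign each cluster's members the cluster family in the truth so
  # the vote is unanimous; rebuild primary-hit subject families to match
  hits <- ht$hits
  ref <- ht$reference
  for (k in seq_len(n_clusters)) {
    for (q in qs[[k]]) {
      best <- which(hits$query_id == q &
                      hits$bitscore == max(hits$bitscore[hits$query_id == q]))
      sid <- hits$subject_id[best[1]]
      ref$family[ref$protein_id == sid] <- cl_fam[k]
    }
  }
  panel <- paste0("Sp", 1:6)
  clusters <- data.frame(
    gene_id = unlist(qs),
    species_id = rep(panel, length.out = n_clusters * members_per_cluster),
    cluster_id = rep(paste0("cl", seq_len(n_clusters)),
                     each = members_per_cluster),
    stringsAsFactors = FALSE)
  trees <- list(); partitions <- list(); taxonomy <- NULL
  for (k in seq_len(n_clusters)) {
    n_anc <- sample(0:(focal_per_cluster - 1), 1)
    g <- gen_gene_tree(focal_per_cluster, n_anc, seed = seed + k)
    trees[[paste0("cl", k)]] <- g$tree
    partitions[[paste0("cl", k)]] <- g$partition
    taxonomy <- g$taxonomy
  }
  focal_rows <- do.call(rbind, lapply(names(trees), function(cid) {
    tr <- trees[[cid]]
    data.frame(gene_id = tr$gene[tr$species == "Trire2"],
               species_id = "Trire2", cluster_id = cid,
               stringsAsFactors = FALSE)
  }))
  # focal gene ids are per-tree; make them unique across clusters
  for (cid in names(trees)) {
    sel <- focal_rows$cluster_id == cid
    focal_rows$gene_id[sel] <- paste0(cid, "_", focal_rows$gene_id[sel])
    tr <- trees[[cid]]
    idx <- tr$species == "Trire2"
    tr$gene[idx] <- paste0(cid, "_", tr$gene[idx])
    trees[[cid]] <- tr
    partitions[[cid]] <- lapply(partitions[[cid]],
                                function(p) paste0(cid, "_", p))
  }
  taxonomy <- species_taxonomy(
    "Trire2", c("Trire2", "Fusox1"),
    c("Trire2", "Fusox1", paste0("Out0", 1:3), panel))
  list(hits = hits, reference = ref,
       clusters = rbind(clusters, focal_rows), trees = trees,
       taxonomy = taxonomy, truth_membership = ht$truth,
       truth_family = stats::setNames(cl_fam, paste0("cl",
                                                     seq_len(n_clusters))),
       truth_partitions = partitions)
}
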