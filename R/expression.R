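# Induction analysis of log2 expression data: per-substrate, per-time
# contrasts against uninduced controls, empirical-Bayes moderated t,
# thresholded induction calls and their summaries.

#' Substrate codes of the induction experiment
#'
#' BO ground bagasse; BS steam-exploded bagasse; BE enzymatically
#' hydrolysed steam-exploded bagasse; XO oat spelt xylan; XB birch xylan;
#' AV1 1% Avicel cellulose; AV0.75 0.75% Avicel cellulose; WH
#' steam-exploded wheat straw; SP steam-exploded spruce; SO sophorose.
#'
#' @export
SUBSTRATES <- c("BO", "BS", "BE", "XO", "XB", "AV1", "AV0.75", "WH",
                "SP", "SO")

#' Time points of the induction experiment, in hours
#' @export
TIMEPOINTS <- c(0, 6, 17, 41, 65)

# which cultivation set each substrate belongs to; controls exist in both
DEFAULT_BATCHES <- c(AV0.75 = 1, WH = 1, SP = 1, SO = 1,
                     BO = 2, BS = 2, BE = 2, XO = 2, XB = 2, AV1 = 2)

#' Build an expression dataset
#'
#' Couples a genes-by-samples matrix of log2 signal intensities with its
#' sample sheet. Columns of the matrix must match the sheet's
#' `sample_id`s one-to-one.
#'
#' @param mat Numeric matrix, rows genes (rownames = gene ids), columns
#'   samples.
#' @param samples Data frame with columns `sample_id`, `substrate`
#'   (`"CONTROL"` for uninduced cultures), `time_h`, `replicate`, `batch`.
#' @return A list of class `expr_dataset`.
#' @export
expr_dataset <- function(mat, samples) {
  need <- c("sample_id", "substrate", "time_h", "replicate", "batch")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(colnames(mat)))
    stop("expression matrix must have sample ids as column names")
  orphan <- setdiff(colnames(mat), samples$sample_id)
  if (length(orphan))
    stop("samples missing from sheet: ", paste(orphan, collapse = ", "))
  orphan2 <- setdiff(samples$sample_id, colnames(mat))
  if (length(orphan2))
    stop("sheet samples missing from matrix: ",
         paste(orphan2, collapse = ", "))
  if (any(!is.finite(mat)))
    stop("expression matrix contains non-finite values")
  samples <- samples[match(colnames(mat), samples$sample_id), ]
  structure(list(mat = mat, samples = samples), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expr_dataset:", nrow(x$mat), "genes x", ncol(x$mat), "samples;",
      length(setdiff(unique(x$samples$substrate), "CONTROL")),
      "substrates\n")
  invisible(x)
}

#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix file has `gene_id` as its first column and one column per
#' sample; the sheet has header `sample_id`, `substrate`, `time_h`,
#' `replicate`, `batch`.
#'
#' @param matrix_path,sheet_path Paths to the two TSV files.
#' @return An `expr_dataset`.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- as.character(raw[[1]])
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  expr_dataset(mat, sheet)
}

#' Write an expression dataset to TSV
#'
#' @param data An `expr_dataset`.
#' @param matrix_path,sheet_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(data, matrix_path, sheet_path) {
  out <- data.frame(gene_id = rownames(data$mat), data$mat,
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

stratum_columns <- function(data, substrate, time_h, batch) {
  s <- data$samples
  s$sample_id[s$substrate == substrate & s$time_h == time_h &
                s$batch == batch]
}

substrate_batch <- function(data, substrate) {
  b <- unique(data$samples$batch[data$samples$substrate == substrate])
  if (!length(b))
    stop("no samples for substrate ", substrate)
  b[1]
}

#' Log2 fold change of an induced culture against its control
#'
#' Mean log2 signal of the induced replicates minus the mean of the
#' uninduced control replicates at the same time point, within the same
#' cultivation batch.
#'
#' @param data An `expr_dataset`.
#' @param substrate Substrate code (not `"CONTROL"`).
#' @param time_h Time point in hours.
#' @param genes Gene ids (default: all genes).
#' @return Named numeric vector of log2 fold changes.
#' @export
fold_change_contrast <- function(data, substrate, time_h, genes = NULL) {
  g <- contrast_groups(data, substrate, time_h)
  if (is.null(genes)) genes <- rownames(data$mat)
  rowMeans(data$mat[genes, g$induced, drop = FALSE]) -
    rowMeans(data$mat[genes, g$control, drop = FALSE])
}

contrast_groups <- function(data, substrate, time_h) {
  batch <- substrate_batch(data, substrate)
  ind <- stratum_columns(data, substrate, time_h, batch)
  ctl <- stratum_columns(data, "CONTROL", time_h, batch)
  if (!length(ind))
    stop("missing stratum: substrate=", substrate, " time_h=", time_h,
         " batch=", batch)
  if (!length(ctl))
    stop("missing stratum: substrate=CONTROL time_h=", time_h,
         " batch=", batch)
  list(induced = ind, control = ctl, batch = batch)
}

#' Moment estimation of the variance prior
#'
#' Fits the scaled inverse-chi-squared prior of the empirical-Bayes
#' variance model to a set of per-gene sample variances with common
#' residual df, by method of moments on the log variances
#' (digamma/trigamma matching). A non-positive between-gene moment yields
#' an infinite prior df (complete shrinkage).
#'
#' @param variances Positive per-gene sample variances (length >= 2).
#' @param df Residual degrees of freedom of each variance.
#' @return List with `d0` (prior df, possibly `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
moderated_variance <- function(variances, df) {
  variances <- variances[is.finite(variances)]
  if (length(variances) < 2)
    stop("need at least 2 finite variances")
  if (any(variances < 0)) stop("variances must be non-negative")
  if (max(variances) - min(variances) == 0)
    return(list(d0 = Inf, s0_sq = variances[1]))
  if (any(variances == 0)) variances <- pmax(variances, 1e-300)
  z <- log(variances)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone)
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated two-sample t-statistic and p-value
#'
#' Pools the within-gene variance across the two groups (df n1+n2-2),
#' shrinks it toward the prior `s0_sq` with weight `d0`, and refers the
#' resulting t-statistic to a t-distribution with `d0 + n1 + n2 - 2`
#' degrees of freedom. `d0 = 0` recovers the classical pooled t-test;
#' `d0 = Inf` uses the prior variance exactly and a normal reference.
#'
#' @param x,y Numeric vectors (induced and control replicates, each of
#'   length >= 2).
#' @param d0,s0_sq Variance prior from [moderated_variance()].
#' @return List with `t_stat`, `p_value`, `lfc` (mean(x) - mean(y)) and
#'   `df_total`.
#' @export
moderated_t_p <- function(x, y, d0, s0_sq) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  dg <- n1 + n2 - 2
  sg_sq <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / dg
  if (is.infinite(d0)) {
    s_tilde <- s0_sq
    df_total <- Inf
  } else {
    s_tilde <- (d0 * s0_sq + dg * sg_sq) / (d0 + dg)
    df_total <- d0 + dg
  }
  diff <- mean(x) - mean(y)
  se <- sqrt(s_tilde * (1 / n1 + 1 / n2))
  if (se == 0) {
    warning("zero posterior variance; p-value set to 0")
    t_stat <- sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    t_stat <- diff / se
    p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat))
         else 2 * stats::pt(-abs(t_stat), df_total)
  }
  list(t_stat = t_stat, p_value = p, lfc = diff, df_total = df_total)
}

#' Ternary induction call from dual thresholds
#'
#' `+1` (induced) when p < `p_max` and lfc > `lfc_min`; `-1` (repressed)
#' when p < `p_max` and lfc < `-lfc_min`; otherwise `0`. All inequalities
#' are strict, so an lfc exactly at the threshold is not called.
#'
#' @param lfc,p_value Numeric vectors (recycled together).
#' @param p_max Significance cut-off (default 0.01).
#' @param lfc_min Log2 fold-change cut-off (default 0.4).
#' @return Integer vector of -1, 0, +1.
#' @export
call_induction <- function(lfc, p_value, p_max = 0.01, lfc_min = 0.4) {
  sig <- p_value < p_max
  ifelse(sig & lfc > lfc_min, 1L, ifelse(sig & lfc < -lfc_min, -1L, 0L))
}

#' All induced-vs-control contrasts of a dataset
#'
#' For every non-control substrate and every time point present in both
#' the induced and the control stratum of the substrate's batch, computes
#' the per-gene log2 fold change and the moderated t-test. The variance
#' prior is estimated per contrast from the pooled within-gene variances
#' of that contrast (set `moderated = FALSE` for the plain pooled t-test,
#' i.e. `d0 = 0`).
#'
#' @param data An `expr_dataset`.
#' @param p_max,lfc_min Call thresholds, see [call_induction()].
#' @param moderated Use the empirical-Bayes prior (default `TRUE`).
#' @return Data frame of class `contrast_table` with columns `gene_id`,
#'   `substrate`, `time_h`, `lfc`, `t_stat`, `p_value`, `call`.
#' @export
contrast_table <- function(data, p_max = 0.01, lfc_min = 0.4,
                           moderated = TRUE) {
  subs <- setdiff(unique(data$samples$substrate), "CONTROL")
  out <- list()
  for (sb in subs) {
    batch <- substrate_batch(data, sb)
    times <- sort(unique(
      data$samples$time_h[data$samples$substrate == sb]))
    for (tp in times) {
      ctl <- stratum_columns(data, "CONTROL", tp, batch)
      if (!length(ctl)) next
      g <- contrast_groups(data, sb, tp)
      xi <- data$mat[, g$induced, drop = FALSE]
      yi <- data$mat[, g$control, drop = FALSE]
      n1 <- ncol(xi); n2 <- ncol(yi)
      dg <- n1 + n2 - 2
      vx <- apply(xi, 1, stats::var)
      vy <- apply(yi, 1, stats::var)
      sg_sq <- ((n1 - 1) * vx + (n2 - 1) * vy) / dg
      if (moderated) {
        pr <- moderated_variance(sg_sq, dg)
      } else {
        pr <- list(d0 = 0, s0_sq = 0)
      }
      if (is.infinite(pr$d0)) {
        s_tilde <- rep(pr$s0_sq, length(sg_sq))
        df_total <- Inf
      } else {
        s_tilde <- (pr$d0 * pr$s0_sq + dg * sg_sq) / (pr$d0 + dg)
        df_total <- pr$d0 + dg
      }
      lfc <- rowMeans(xi) - rowMeans(yi)
      se <- sqrt(s_tilde * (1 / n1 + 1 / n2))
      t_stat <- lfc / se
      p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat))
           else 2 * stats::pt(-abs(t_stat), df_total)
      p[se == 0 & lfc != 0] <- 0
      p[se == 0 & lfc == 0] <- 1
      out[[length(out) + 1]] <- data.frame(
        gene_id = rownames(data$mat), substrate = sb, time_h = tp,
        lfc = unname(lfc), t_stat = unname(t_stat), p_value = unname(p),
        call = call_induction(unname(lfc), unname(p), p_max, lfc_min),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("contrast_table", class(res))
  res
}

#' Genes induced by at least one substrate
#'
#' @param calls A `contrast_table` (or any data frame with `gene_id`,
#'   `substrate`, `call`).
#' @return Character vector of gene ids with at least one `+1` call on a
#'   non-control substrate.
#' @export
induced_gene_set <- function(calls) {
  up <- calls$call == 1L & calls$substrate != "CONTROL"
  sort(unique(calls$gene_id[up]))
}

#' Core set of genes induced across substrate classes
#'
#' Genes induced (at any time point) on at least one cellulose-class and
#' at least one xylan-class substrate, and on at least
#' `ceiling(fraction * n_substrates)` distinct substrates overall.
#'
#' @param calls A `contrast_table`.
#' @param class_map Named character vector mapping each non-control
#'   substrate to `"cellulose"`, `"xylan"` or `"other"`.
#' @param fraction Minimal fraction of substrates showing induction
#'   (default 0.70).
#' @return Character vector of gene ids.
#' @export
core_induced_set <- function(calls, class_map, fraction = 0.70) {
  subs <- setdiff(unique(calls$substrate), "CONTROL")
  miss <- setdiff(subs, names(class_map))
  if (length(miss))
    stop("class_map lacks substrate(s): ", paste(miss, collapse = ", "))
  need_n <- ceiling(fraction * length(subs))
  up <- calls[calls$call == 1L & calls$substrate != "CONTROL", ,
              drop = FALSE]
  by_gene <- split(up$substrate, up$gene_id)
  ok <- vapply(by_gene, function(s) {
    s <- unique(s)
    any(class_map[s] == "cellulose") && any(class_map[s] == "xylan") &&
      length(s) >= need_n
  }, TRUE)
  sort(names(by_gene)[ok])
}

#' Family-by-substrate induction count matrix
#'
#' Cell (family, substrate) counts the genes of that family with a `+1`
#' call at any time point on that substrate. Genes absent from the
#' annotation are counted under `"UNASSIGNED"` with a warning. Margins
#' report, per substrate, the number of induced genes and the number of
#' families with at least one induced gene.
#'
#' @param calls A `contrast_table`.
#' @param annotation Named character vector (gene id -> family) or an
#'   annotation table data frame with `gene_id` and `family` columns.
#' @return List with `matrix` (families x substrates integer matrix),
#'   `genes_per_substrate` and `families_per_substrate`.
#' @export
family_induction_matrix <- function(calls, annotation) {
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation$family, annotation$gene_id)
  subs <- setdiff(unique(calls$substrate), "CONTROL")
  up <- calls[calls$call == 1L & calls$substrate %in% subs, , drop = FALSE]
  fam <- unname(annotation[up$gene_id])
  if (anyNA(fam)) {
    warning("genes without family annotation counted as UNASSIGNED: ",
            paste(unique(up$gene_id[is.na(fam)]), collapse = ", "))
    fam[is.na(fam)] <- "UNASSIGNED"
  }
  pairs <- unique(data.frame(gene_id = up$gene_id, family = fam,
                             substrate = up$substrate,
                             stringsAsFactors = FALSE))
  fams <- sort(unique(c(fam, character(0))))
  m <- matrix(0L, nrow = length(fams), ncol = length(subs),
              dimnames = list(fams, subs))
  if (nrow(pairs)) {
    tb <- table(pairs$family, pairs$substrate)
    m[rownames(tb), colnames(tb)] <- as.integer(tb)
  }
  list(matrix = m,
       genes_per_substrate = vapply(subs, function(s)
         length(unique(pairs$gene_id[pairs$substrate == s])), 1L),
       families_per_substrate = vapply(subs, function(s)
         length(unique(pairs$family[pairs$substrate == s])), 1L))
}

#' Fold change at the time of maximal induction
#'
#' For each gene and substrate, the log2 fold change at the time point
#' where it is maximal (the value itself, which may be negative when the
#' gene is never induced on that substrate).
#'
#' @param calls A `contrast_table` (uses its `lfc` column).
#' @return Numeric matrix genes x substrates.
#' @export
max_induction_profile <- function(calls) {
  calls <- calls[calls$substrate != "CONTROL", , drop = FALSE]
  genes <- unique(calls$gene_id)
  subs <- unique(calls$substrate)
  m <- matrix(NA_real_, length(genes), length(subs),
              dimnames = list(genes, subs))
  agg <- stats::aggregate(lfc ~ gene_id + substrate, data = calls, FUN = max)
  m[cbind(agg$gene_id, agg$substrate)] <- agg$lfc
  m
}

#' Cut a fold-change heatmap into co-expression branches
#'
#' Agglomerative hierarchical clustering of the gene fold-change profiles
#' (complete linkage on Euclidean distance by default), cut into `k`
#' branches labelled `A`, `B`, ... in order of the first member gene in
#' input (row) order. The labelling is deterministic given the row order;
#' permuting rows permutes only the labels, not the partition.
#'
#' @param lfc_matrix Numeric matrix, genes x conditions.
#' @param k Number of branches (default 18).
#' @param method Linkage passed to [stats::hclust()].
#' @param metric Distance passed to [stats::dist()].
#' @return Named character vector gene id -> branch label.
#' @export
cluster_coexpression_branches <- function(lfc_matrix, k = 18,
                                          method = "complete",
                                          metric = "euclidean") {
  n <- nrow(lfc_matrix)
  if (k < 1 || k > n)
    stop("k must be between 1 and the number of genes (", n, ")")
  if (any(!is.finite(lfc_matrix)))
    stop("lfc matrix contains non-finite values")
  grp <- if (k == 1) rep(1L, n) else
    stats::cutree(stats::hclust(stats::dist(lfc_matrix, method = metric),
                                method = method), k = k)
  first <- tapply(seq_len(n), grp, min)
  relabel <- stats::setNames(seq_along(first), names(sort(first)))
  lab <- subgroup_letters(k)
  labs <- toupper(lab)[relabel[as.character(grp)]]
  stats::setNames(labs, rownames(lfc_matrix))
}
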