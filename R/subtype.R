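#' Subject-similarity distance matrix
#'
#' The two-step similarity construction used for anatomical subtyping:
#' (1) the pairwise Pearson correlation matrix of the subjects' in-mask
#' voxel vectors (subjects x subjects, unit diagonal); (2) the Euclidean
#' distance between the rows of that correlation matrix. An alternative
#' `1 - r` dissimilarity is available behind a flag.
#'
#' @param features a [extract_features()] matrix or plain subjects x voxels
#'   matrix (>= 3 subjects, >= 2 voxels).
#' @param method `"correlation-rows"` (distance between correlation-matrix
#'   rows, the default) or `"one-minus-r"`.
#' @return symmetric distance matrix with subject ids as dimnames.
#' @export
subject_similarity <- function(features,
                               method = c("correlation-rows", "one-minus-r")) {
  method <- match.arg(method)
  values <- if (inherits(features, "svd_features")) features$values else features
  values <- as.matrix(values)
  if (nrow(values) < 3L) stop("need >= 3 subjects")
  if (ncol(values) < 2L) stop("need >= 2 voxels")
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance subject vector(s): ",
         paste(rownames(values)[sds == 0], collapse = ", "))
  R <- stats::cor(t(values))
  D <- if (method == "correlation-rows") as.matrix(stats::dist(R)) else 1 - R
  if (method == "one-minus-r") diag(D) <- 0
  dimnames(D) <- list(rownames(values), rownames(values))
  D
}

#' Ward-linkage dendrogram
#'
#' Agglomerative Ward minimum-variance clustering of a subject distance
#' matrix, using the Ward.D2 convention (squared-distance Lance-Williams
#' update on Euclidean inputs), which guarantees weakly increasing merge
#' heights.
#'
#' @param distances symmetric, zero-diagonal, non-negative distance matrix
#'   (or a `dist`).
#' @return object of class `svd_linkage`: the underlying `hclust` tree plus
#'   a merge table (`node_a`, `node_b`, `height`, `size`) and leaf ids.
#' @export
ward_linkage <- function(distances) {
  if (is.matrix(distances)) {
    if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-10)))
      stop("distance matrix must be symmetric")
    if (any(diag(distances) != 0)) stop("distance matrix diagonal must be zero")
    if (any(distances < 0)) stop("distances must be non-negative")
    labels <- rownames(distances)
    distances <- stats::as.dist(distances)
  } else labels <- attr(distances, "Labels")
  hc <- stats::hclust(distances, method = "ward.D2")
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(x) if (x < 0) 1L else sizes[x]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  structure(list(hclust = hc,
                 merges = data.frame(node_a = hc$merge[, 1],
                                     node_b = hc$merge[, 2],
                                     height = hc$height, size = sizes),
                 leaf_ids = if (is.null(labels))
                   as.character(seq_len(nrow(hc$merge) + 1L)) else labels),
            class = "svd_linkage")
}

#' @export
print.svd_linkage <- function(x, ...) {
  cat(sprintf("<svd_linkage> %d leaves, Ward.D2, height range [%.3g, %.3g]\n",
              length(x$leaf_ids), min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Cut a Ward tree into k subtypes
#'
#' Cuts the dendrogram at the height giving exactly `k` clusters (default
#' 4, the number of anatomical subgroups the analysis targets; the tree is
#' exported so the cut can be inspected visually). Labels are renumbered
#' deterministically by dendrogram left-to-right order. Tied merge heights
#' that prevent an exact-k cut are resolved in favour of the earlier merge,
#' with a warning.
#'
#' @param tree a [ward_linkage()] tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels (1..k) named by leaf id.
#' @export
cut_tree <- function(tree, k = 4L) {
  hc <- tree$hclust
  n <- length(tree$leaf_ids)
  stopifnot(k >= 1L, k <= n)
  h <- hc$height
  if (k > 1L && k < n && h[n - k] == h[n - k + 1L])
    warning("tied merge heights at the requested cut; earlier merge wins")
  raw <- stats::cutree(hc, k = k)
  # renumber by left-to-right dendrogram order
  first_seen <- unique(raw[hc$order])
  labels <- match(raw, first_seen)
  stats::setNames(as.integer(labels), tree$leaf_ids)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions corrected for chance; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones. Used to score
#' subtype recovery against the generator's planted subtypes.
#'
#' @param a,b integer/factor partitions of the same subjects.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Subgroup summary table
#'
#' Per-subtype summary of the convertor cohort in the shape of the
#' subgroup-characteristics table: n, percent correctly predicted by the
#' SVM, mean (SD) of demographics, MRI volumetrics and cognitive baseline
#' indices, time to onset, and the mean hippocampal contraction rate where
#' rate maps are supplied.
#'
#' @param labels named subtype assignment from [cut_tree()] (convertors).
#' @param cohort a [cohort_table()].
#' @param volumetrics optional [volumetrics_table()] output.
#' @param prediction optional [loo_predict()] result on the full cohort.
#' @param hippocampal_rates optional named numeric of per-subject mean
#'   hippocampal rates (from [roi_mean_rate()]).
#' @return data frame, one row per subtype.
#' @export
subgroup_summary <- function(labels, cohort, volumetrics = NULL,
                             prediction = NULL, hippocampal_rates = NULL) {
  subj <- cohort$subjects
  ids <- names(labels)
  miss <- setdiff(subj$id[subj$converted], ids)
  if (length(miss))
    stop("labels must cover all convertors; missing: ",
         paste(miss, collapse = ", "))
  base_cog <- NULL
  if (!is.null(cohort$visits)) {
    v0 <- cohort$visits[cohort$visits$time == 0, ]
    base_cog <- v0[match(ids, v0$id), intersect(COG_DOMAINS, names(v0))]
  }
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
  }
  rows <- lapply(sort(unique(labels)), function(g) {
    gi <- ids[labels == g]
    if (!length(gi)) stop("subtype group of size 0")
    si <- subj[match(gi, subj$id), ]
    row <- data.frame(subtype = g, n = length(gi))
    if (!is.null(prediction)) {
      pi <- match(gi, subj$id)
      correct <- prediction$predicted[pi] == prediction$labels[pi]
      row$correctly_predicted_pct <- 100 * mean(correct)
    }
    add_msd <- function(row, nm, x) {
      s <- msd(x)
      row[[paste0(nm, "_mean")]] <- s[["mean"]]
      row[[paste0(nm, "_sd")]] <- s[["sd"]]
      row
    }
    row <- add_msd(row, "age", si$age)
    row$male_pct <- 100 * mean(si$sex == "male")
    row <- add_msd(row, "mmse", si$mmse)
    row <- add_msd(row, "nart", si$nart)
    row <- add_msd(row, "rankin", si$rankin)
    row <- add_msd(row, "onset_years", si$event_time)
    if (!is.null(volumetrics)) {
      vi <- volumetrics[match(gi, volumetrics$id), ]
      for (nm in c("gm_mm3", "wm_mm3", "wmh_mm3", "lacune_mm3",
                   "tcv_mm3", "svdp_percent"))
        row <- add_msd(row, sub("_mm3$|_percent$", "", nm), vi[[nm]])
    }
    if (!is.null(base_cog))
      for (dmn in names(base_cog))
        row <- add_msd(row, paste0("cog_", dmn), base_cog[labels == g, dmn])
    if (!is.null(hippocampal_rates))
      row <- add_msd(row, "hippocampal_rate", hippocampal_rates[gi])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
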