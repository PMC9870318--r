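.param_sets <- list(
  three = c("ih_140", "sag_80", "rebound_80"),
  six = c("ih_140", "sag_80", "rebound_80", "mfr_step", "fsl_10",
          "first_isi_40"))

#' Assemble the clustering feature matrix
#'
#' Builds the three- or six-parameter matrix used for unbiased
#' categorization. The three-parameter set is Ih density at -140 mV, voltage
#' sag at -80 pA and the number of rebound spikes at -80 pA; the
#' six-parameter set adds the current step giving the maximum firing rate,
#' first-spike latency at +10 pA and first ISI at +40 pA. Neurons lacking
#' any selected parameter are dropped (and reported via the `dropped`
#' attribute); for the six-parameter set, neurons labeled `"Others"` are
#' excluded a priori since they have no FSL at +10 pA or first ISI at
#' +40 pA. Excluded neurons are never included.
#'
#' @param features Feature tibble from [extract_features()], optionally with
#'   `label` / `excluded` columns from [classify_neurons()].
#' @param parameter_set `"three"` or `"six"`.
#' @return Tibble `neuron_id` plus the selected parameter columns; rows
#'   dropped for missing values are listed in `attr(, "dropped")`.
#' @export
build_feature_matrix <- function(features, parameter_set = c("three", "six")) {
  parameter_set <- match.arg(parameter_set)
  cols <- .param_sets[[parameter_set]]
  miss <- setdiff(cols, names(features))
  if (length(miss))
    abort(paste0("feature table lacks columns: ", paste(miss, collapse = ", ")))
  d <- features
  if ("excluded" %in% names(d)) d <- filter(d, !.data$excluded)
  if (parameter_set == "six" && "label" %in% names(d))
    d <- filter(d, .data$label != "Others")
  keep <- complete.cases(d[cols])
  out <- d[keep, c("neuron_id", cols)]
  attr(out, "dropped") <- d$neuron_id[!keep]
  out
}

#' Column standardization (z-score)
#'
#' @param mat Tibble from [build_feature_matrix()] (`neuron_id` + numeric
#'   columns) or a plain numeric data frame.
#' @return The standardized tibble; per-column `center` and `scale` are
#'   stored as attributes so the transform can be inverted with
#'   [unstandardize()].
#' @export
standardize <- function(mat) {
  num <- setdiff(names(mat), "neuron_id")
  const <- num[purrr::map_lgl(num, ~ sd(mat[[.x]]) == 0 || is.na(sd(mat[[.x]])))]
  if (length(const))
    abort(paste0("constant column(s) cannot be standardized: ",
                 paste(const, collapse = ", ")))
  center <- purrr::map_dbl(mat[num], mean)
  scl <- purrr::map_dbl(mat[num], sd)
  out <- mat
  for (cn in num) out[[cn]] <- (mat[[cn]] - center[[cn]]) / scl[[cn]]
  attr(out, "center") <- center
  attr(out, "scale") <- scl
  out
}

#' @rdname standardize
#' @param z A tibble produced by [standardize()].
#' @export
unstandardize <- function(z) {
  center <- attr(z, "center")
  scl <- attr(z, "scale")
  if (is.null(center)) abort("`z` carries no standardization attributes")
  out <- z
  for (cn in names(center)) out[[cn]] <- z[[cn]] * scl[[cn]] + center[[cn]]
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Ward agglomerative clustering (ward.D2)
#'
#' Agglomerates rows under Ward's minimum-variance criterion on Euclidean
#' distances: at each step the pair of clusters whose merge least increases
#' the total within-cluster sum of squares is joined, and the recorded
#' height is `sqrt(2 * delta_SS)` — identical to `hclust(method =
#' "ward.D2")` on a Euclidean distance matrix. Ties are broken toward the
#' pair of lowest cluster indices (creation order), making the merge
#' sequence fully deterministic.
#'
#' @param mat Tibble from [build_feature_matrix()] (optionally
#'   [standardize()]d) or a numeric matrix; a `neuron_id` column provides
#'   the labels.
#' @param scale Standardize columns before clustering (default `TRUE`; the
#'   parameters mix pA/pF, mV, ms and counts, so unscaled Euclidean distance
#'   would be dominated by the largest-magnitude column).
#' @return An object of class `c("ward_linkage", "hclust")`: `merge`,
#'   `height`, `order`, `labels` in `hclust` conventions, so
#'   [stats::cutree()], `plot()` and [ape::as.phylo()] apply.
#' @export
ward_linkage <- function(mat, scale = TRUE) {
  labels <- if (is.data.frame(mat) && "neuron_id" %in% names(mat)) {
    mat$neuron_id
  } else {
    rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  if (is.data.frame(mat)) {
    if (scale) mat <- standardize(mat)
    x <- as.matrix(mat[setdiff(names(mat), "neuron_id")])
  } else {
    x <- as.matrix(mat)
    if (scale && ncol(x) > 1) x <- base::scale(x)
  }
  n <- nrow(x)
  if (n < 2) abort("ward_linkage needs at least 2 rows")

  # active clusters: centroid, size, id (negative leaf / positive merge step)
  cent <- lapply(seq_len(n), function(i) x[i, ])
  size <- rep(1, n)
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    m <- length(size)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        d2 <- sum((cent[[i]] - cent[[j]])^2)
        cost <- size[i] * size[j] / (size[i] + size[j]) * d2
        if (cost < best[1] - 1e-12) best <- c(cost, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    pair <- sort(c(id[i], id[j]))
    merge[s, ] <- pair
    height[s] <- sqrt(2 * best[1])
    w <- size[i] + size[j]
    cent[[i]] <- (size[i] * cent[[i]] + size[j] * cent[[j]]) / w
    size[i] <- w
    id[i] <- s
    cent[[j]] <- NULL
    size <- size[-j]
    id <- id[-j]
  }

  ord <- integer(0)
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  structure(list(merge = merge, height = height, order = walk(n - 1),
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = c("ward_linkage", "hclust"))
}

#' Cut a linkage tree into k clusters
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of clusters.
#' @return Tibble `neuron_id`, `cluster` (integers 1..k).
#' @export
cut_clusters <- function(tree, k) {
  cl <- cutree(tree, k = k)
  tibble(neuron_id = tree$labels, cluster = unname(cl))
}

#' Cluster-versus-type agreement
#'
#' Cross-tabulates unbiased cluster assignments against visual type labels
#' and reports each cluster's majority type and purity.
#'
#' @param clusters Tibble from [cut_clusters()].
#' @param labels Tibble with `neuron_id` and `label`.
#' @return List of class `cluster_agreement`: `contingency` (tibble
#'   `cluster`, `label`, `n`), `purity` (per-cluster majority label, size,
#'   purity in `[0, 1]`), and `overall` purity.
#' @export
cluster_agreement <- function(clusters, labels) {
  d <- left_join(clusters, labels[c("neuron_id", "label")], by = "neuron_id")
  cont <- count(d, .data$cluster, .data$label, name = "n")
  pur <- cont |>
    group_by(.data$cluster) |>
    summarise(n = sum(.data$n),
              majority_label = .data$label[which.max(.data$n)],
              purity = max(.data$n) / sum(.data$n),
              .groups = "drop")
  structure(list(contingency = cont, purity = pur,
                 overall = sum(pur$n * pur$purity) / sum(pur$n)),
            class = "cluster_agreement")
}

#' @export
print.cluster_agreement <- function(x, ...) {
  cat("<cluster_agreement>\n")
  print(x$purity)
  cat(sprintf("overall purity: %.3f\n", x$overall))
  invisible(x)
}

#' Export heatmap data and dendrogram
#'
#' `export_heatmap()` writes a TSV of the (scaled) matrix in dendrogram leaf
#' order plus, optionally, a PNG of the heatmap; `export_dendrogram_newick()`
#' writes the tree in Newick format (branch lengths halve each merge height,
#' so leaves sit at depth height/2 of their cluster).
#'
#' @param mat Feature-matrix tibble (the values to draw; pass a
#'   [standardize()]d matrix for a z-scored heatmap).
#' @param tree Matching [ward_linkage()] tree.
#' @param labels Optional tibble `neuron_id`, `label` for row annotation.
#' @param path_tsv Output TSV path.
#' @param path_png Optional output PNG path.
#' @return Invisibly, the row-ordered tibble that was written.
#' @export
export_heatmap <- function(mat, tree, labels = NULL, path_tsv,
                           path_png = NULL) {
  ordered <- mat[match(tree$labels[tree$order], mat$neuron_id), ]
  if (!is.null(labels))
    ordered <- left_join(ordered, labels[c("neuron_id", "label")],
                         by = "neuron_id")
  readr::write_tsv(ordered, path_tsv)
  if (!is.null(path_png)) {
    p <- plot_feature_heatmap(mat, tree, labels)
    ggplot2::ggsave(path_png, p, width = 6, height = 7, dpi = 150)
  }
  invisible(ordered)
}

#' @rdname export_heatmap
#' @param path Output Newick path.
#' @export
export_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' Raw-value 3D scatter table
#'
#' The three-parameter summary scatter of visual classification: evoked
#' spikes at +60 pA, rebound spikes at -80 pA and voltage sag at -80 pA, as
#' raw (unscaled) values, one row per neuron with all three present.
#'
#' @param features Feature tibble (needs `evoked_60`, `rebound_80`,
#'   `sag_80`).
#' @param labels Optional tibble `neuron_id`, `label`.
#' @return Tibble `neuron_id`, `evoked_60`, `rebound_80`, `sag_80`
#'   (+ `label`).
#' @export
scatter3d_export <- function(features, labels = NULL) {
  cols <- c("evoked_60", "rebound_80", "sag_80")
  out <- features[c("neuron_id", cols)]
  out <- out[complete.cases(out[cols]), ]
  if (!is.null(labels))
    out <- left_join(out, labels[c("neuron_id", "label")], by = "neuron_id")
  as_tibble(out)
}
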