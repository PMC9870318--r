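#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted objects: `ephys_anova`,
#' `ephys_tukey`, `ward_linkage` and `cluster_agreement`.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name patchtype-tidiers
NULL

#' @rdname patchtype-tidiers
#' @export
tidy.ephys_anova <- function(x, ...) x$table

#' @rdname patchtype-tidiers
#' @export
glance.ephys_anova <- function(x, ...) {
  tibble(type = x$type,
         n = sum(x$cells$n),
         n_cells = nrow(x$cells),
         min_cell_n = min(x$cells$n))
}

#' @rdname patchtype-tidiers
#' @export
tidy.ephys_tukey <- function(x, ...) x$table

#' @rdname patchtype-tidiers
#' @export
glance.ephys_tukey <- function(x, ...) {
  tibble(n_contrasts = nrow(x$table), conf.level = x$conf.level)
}

#' @rdname patchtype-tidiers
#' @export
tidy.ward_linkage <- function(x, ...) {
  tibble(step = seq_along(x$height),
         left = x$merge[, 1], right = x$merge[, 2],
         height = x$height,
         size = purrr::map_int(seq_along(x$height), function(s) {
           count_leaves <- function(k) {
             if (k < 0) return(1L)
             count_leaves(x$merge[k, 1]) + count_leaves(x$merge[k, 2])
           }
           count_leaves(s)
         }))
}

#' @rdname patchtype-tidiers
#' @export
glance.ward_linkage <- function(x, ...) {
  tibble(n = length(x$labels),
         n_merges = length(x$height),
         max_height = max(x$height),
         method = x$method)
}

#' @rdname patchtype-tidiers
#' @export
tidy.cluster_agreement <- function(x, ...) x$purity

#' @rdname patchtype-tidiers
#' @export
glance.cluster_agreement <- function(x, ...) {
  tibble(n_clusters = nrow(x$purity),
         n = sum(x$purity$n),
         overall_purity = x$overall)
}
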