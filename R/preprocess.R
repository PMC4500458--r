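#' Convert abundances to within-plot relative abundances
#'
#' Divides every species' abundance by its plot's total so each plot's entries
#' sum to one (the proportional biomass of each species in the community).
#' Multiplying all abundances in a plot by a positive constant leaves the
#' result unchanged.
#'
#' @param cm Community tibble (`plot_id`, `site_id`, `depth_m`, species columns)
#'   with nonnegative abundances and at least one positive entry per plot.
#' @return A tibble of the same shape whose species columns are proportions.
#' @export
relative_abundance <- function(cm) {
  validate_community_matrix(cm)
  A <- abundance_matrix(cm)
  P <- A / rowSums(A)
  out <- cm
  out[species_names(cm)] <- tibble::as_tibble(P)
  out
}

#' Preprocess traits for the maximum entropy model
#'
#' Applies, in order: natural-log transform to the traits flagged
#' `log_transform` in the metadata; a translation by `+|min|` for any trait
#' column that contains a negative value afterwards (the iterative-scaling
#' fitting algorithm requires nonnegative features); and, if `standardize` is
#' `TRUE`, division of every trait column by its sample standard deviation
#' across species. Columns are scaled, not centered: centering would
#' reintroduce negative values, and the lambda coefficients are invariant to
#' translation, so scaling alone puts all traits on a unit-variance scale where
#' `|lambda|` values are comparable.
#'
#' @param traits Trait table (tibble with `species` column).
#' @param meta Trait metadata; defaults to the attached `"trait_meta"`
#'   attribute. Only its `log_transform` flags are used here.
#' @param standardize Divide each trait by its sample (n-1) standard deviation
#'   across species. Default `TRUE`.
#' @return The preprocessed trait table (all values nonnegative), with the
#'   scale divisors in attribute `"scale"` and metadata carried through.
#' @export
preprocess_traits <- function(traits, meta = attr(traits, "trait_meta"),
                              standardize = TRUE) {
  validate_trait_table(traits, meta)
  out <- traits
  tn <- trait_names(traits)
  logged <- if (!is.null(meta)) meta$trait[meta$log_transform] else character()
  for (j in tn) {
    x <- out[[j]]
    if (j %in% logged) {
      if (any(x <= 0))
        stop("trait '", j, "' has non-positive values; cannot log-transform")
      x <- log(x)
    }
    if (any(x < 0)) x <- x + abs(min(x))
    out[[j]] <- x
  }
  scale_div <- rep(1, length(tn))
  names(scale_div) <- tn
  if (standardize) {
    for (j in tn) {
      s <- sd(out[[j]])
      if (!is.finite(s) || s == 0)
        stop("trait '", j, "' has zero variance; cannot standardize")
      out[[j]] <- out[[j]] / s
      scale_div[j] <- s
    }
  }
  attr(out, "trait_meta") <- meta
  attr(out, "scale") <- scale_div
  out
}

#' Community-weighted mean traits
#'
#' For every plot, the abundance-weighted mean of each trait:
#' \eqn{CWM_j = \sum_i p_i t_{ij}} with \eqn{p_i} the relative abundance of
#' species \eqn{i}. These are the macroscopic constraints of the maxent model.
#' By construction every CWM lies within the range of that trait's species
#' values.
#'
#' @param ra Relative-abundance tibble from [relative_abundance()].
#' @param traits Trait table whose species match `ra`'s species columns, in
#'   order (typically preprocessed with [preprocess_traits()]).
#' @return A tibble `plot_id`, `site_id`, `depth_m` followed by one CWM column
#'   per trait.
#' @export
compute_cwm <- function(ra, traits) {
  sp <- species_names(ra)
  if (!identical(sp, traits$species))
    stop("species of the relative-abundance table and trait table must match, in order")
  P <- abundance_matrix(ra)
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("rows of `ra` must sum to 1; call relative_abundance() first")
  cwm <- P %*% trait_matrix(traits)
  dplyr::bind_cols(ra[c("plot_id", "site_id", "depth_m")],
                   tibble::as_tibble(cwm))
}

cwm_matrix <- function(cwm) {
  m <- as.matrix(cwm[setdiff(names(cwm), c("plot_id", "site_id", "depth_m"))])
  rownames(m) <- cwm$plot_id
  storage.mode(m) <- "double"
  m
}
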