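# shared fixtures and independent oracles for the test suite

extdata <- function(f) system.file("extdata", f, package = "cwmaxent")

erhai_abundance <- function() {
  read_community_matrix(extdata("erhai_mean_abundance.csv"))
}

standin_traits <- function() {
  read_trait_table(extdata("synthetic_standin_traits.csv"),
                   extdata("synthetic_standin_trait_meta.csv"))
}

# minimal metadata for ad-hoc trait tibbles
make_meta <- function(traits, kind = "continuous", log_transform = FALSE) {
  tn <- setdiff(names(traits), "species")
  tibble::tibble(trait = tn,
                 kind = rep_len(kind, length(tn)),
                 log_transform = rep_len(log_transform, length(tn)),
                 unit = "")
}

make_traits <- function(values, ...) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("sp%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m))
  attr(out, "trait_meta") <- make_meta(out, ...)
  out
}

make_cm <- function(A, depth = NULL, site = NULL, species = NULL) {
  A <- as.matrix(A)
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(ncol(A)))
  colnames(A) <- species
  tibble::tibble(plot_id = sprintf("p%02d", seq_len(nrow(A))),
                 site_id = if (is.null(site)) "s1" else as.character(site),
                 depth_m = if (is.null(depth)) 1 else depth) |>
    dplyr::bind_cols(tibble::as_tibble(A))
}

# Independent primal oracle: maximize entropy over {p in simplex : T'p = b}
# by parametrizing the feasible affine set through a known interior feasible
# point p0 (p = p0 + N a, N = null space of rbind(t(T), 1)) and running
# constrOptim on -entropy with the inequality constraints p >= eps. No
# exponential-family structure is used, so this is independent of the solver.
primal_entropy_oracle <- function(T, p0, eps = 1e-9) {
  T <- as.matrix(T)
  A <- rbind(t(T), rep(1, nrow(T)))
  N <- MASS::Null(t(A))             # columns span the feasible directions
  if (ncol(N) == 0) return(p0)
  negent <- function(a) {
    p <- p0 + drop(N %*% a)
    sum(p * log(p))
  }
  grad <- function(a) drop(crossprod(N, log(p0 + drop(N %*% a)) + 1))
  res <- stats::constrOptim(rep(0, ncol(N)), negent, grad,
                            ui = N, ci = eps - p0,
                            outer.iterations = 200,
                            control = list(reltol = 1e-14, maxit = 2000))
  p0 + drop(N %*% res$par)
}
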