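#' Read a species-by-trait table with its metadata
#'
#' Loads a trait table (species in rows, one column per trait) together with a
#' trait metadata table declaring, for every trait, its kind (`"continuous"` or
#' `"binary12"`, the 1 = no / 2 = yes coding used for presence-type traits such
#' as floating leaves, perenniality or tubers), whether it is log-transformed
#' during preprocessing, and its unit.
#'
#' @param path Path to a CSV with a header row of trait names; the first column
#'   holds species identifiers.
#' @param meta_path Path to a CSV with columns `trait`, `kind`, `log_transform`,
#'   `unit`.
#' @return A tibble with column `species` followed by one numeric column per
#'   trait, carrying the metadata tibble in attribute `"trait_meta"`.
#'   Species and trait order are preserved from the file.
#' @export
#' @examples
#' tr <- system.file("extdata", "synthetic_standin_traits.csv", package = "cwmaxent")
#' mt <- system.file("extdata", "synthetic_standin_trait_meta.csv", package = "cwmaxent")
#' traits <- read_trait_table(tr, mt)
read_trait_table <- function(path, meta_path) {
  traits <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(traits)[1] <- "species"
  traits$species <- as.character(traits$species)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            trait = readr::col_character(),
                            kind = readr::col_character(),
                            log_transform = readr::col_logical(),
                            unit = readr::col_character()
                          ))
  meta$unit[is.na(meta$unit)] <- ""
  validate_trait_table(traits, meta)
  attr(traits, "trait_meta") <- meta
  traits
}

#' Validate a trait table against its metadata
#'
#' Checks the invariants a trait table must satisfy before entering the maxent
#' pipeline: no missing values, unique species and trait names, every trait
#' covered by the metadata, and binary-coded (1/2) traits taking no other
#' values.
#'
#' @param traits Tibble with a `species` column followed by numeric trait
#'   columns.
#' @param meta Trait metadata tibble (`trait`, `kind`, `log_transform`, `unit`);
#'   taken from `attr(traits, "trait_meta")` when omitted.
#' @return `traits`, invisibly, on success; otherwise an error.
#' @export
validate_trait_table <- function(traits, meta = attr(traits, "trait_meta")) {
  stopifnot(is.data.frame(traits), names(traits)[1] == "species")
  tn <- trait_names(traits)
  if (anyDuplicated(traits$species))
    stop("duplicate species id: ",
         paste(unique(traits$species[duplicated(traits$species)]), collapse = ", "))
  if (anyDuplicated(tn))
    stop("duplicate trait name: ", paste(unique(tn[duplicated(tn)]), collapse = ", "))
  for (j in tn) {
    col <- traits[[j]]
    if (!is.numeric(col)) stop("trait '", j, "' is not numeric")
    if (anyNA(col))
      stop("missing value for species '",
           traits$species[which(is.na(col))[1]], "', trait '", j, "'")
  }
  if (!is.null(meta)) {
    missing_meta <- setdiff(tn, meta$trait)
    if (length(missing_meta))
      stop("traits without metadata: ", paste(missing_meta, collapse = ", "))
    bad_kind <- setdiff(meta$kind, c("binary12", "continuous"))
    if (length(bad_kind)) stop("unknown trait kind: ", paste(bad_kind, collapse = ", "))
    for (j in intersect(meta$trait[meta$kind == "binary12"], tn)) {
      if (!all(traits[[j]] %in% c(1, 2)))
        stop("binary12 trait '", j, "' has values outside {1, 2}")
    }
  }
  invisible(traits)
}

#' Read a plots-by-species community matrix
#'
#' Loads an abundance CSV whose mandatory leading columns are `plot_id`,
#' `site_id` and `depth_m`, followed by one nonnegative abundance column per
#' species (biomass in kg dry weight per square metre, or any nonnegative mass
#' unit).
#'
#' @param path Path to the abundance CSV.
#' @param traits Optional trait table; when supplied, the species columns are
#'   checked to match the trait table's species in the same order.
#' @return A tibble `plot_id`, `site_id`, `depth_m`, then species columns.
#' @export
read_community_matrix <- function(path, traits = NULL) {
  cm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("plot_id", "site_id", "depth_m")
  if (!all(req %in% names(cm)))
    stop("abundance file must have columns ", paste(req, collapse = ", "))
  cm <- dplyr::relocate(cm, dplyr::all_of(req))
  cm$plot_id <- as.character(cm$plot_id)
  cm$site_id <- as.character(cm$site_id)
  validate_community_matrix(cm, traits)
  cm
}

#' Validate a community matrix
#'
#' @param cm Community tibble (`plot_id`, `site_id`, `depth_m`, species columns).
#' @param traits Optional paired trait table; species names and order must match.
#' @return `cm`, invisibly.
#' @export
validate_community_matrix <- function(cm, traits = NULL) {
  sp <- species_names(cm)
  if (length(sp) < 1) stop("community matrix has no species columns")
  A <- abundance_matrix(cm)
  if (anyNA(A)) stop("missing abundance values")
  if (any(A < 0)) stop("negative abundance values")
  empty <- rowSums(A) <= 0
  if (any(empty))
    stop("plot(s) with no positive abundance: ",
         paste(cm$plot_id[empty], collapse = ", "))
  if (anyDuplicated(cm$plot_id))
    stop("duplicate plot_id: ",
         paste(unique(cm$plot_id[duplicated(cm$plot_id)]), collapse = ", "))
  if (!is.null(traits) && !identical(sp, traits$species))
    stop("species columns must match the trait table's species, in order")
  invisible(cm)
}

#' @rdname read_trait_table
#' @param traits Trait table to write.
#' @param meta Trait metadata tibble; defaults to the attached metadata.
#' @export
write_trait_table <- function(traits, path, meta_path = NULL,
                              meta = attr(traits, "trait_meta")) {
  readr::write_csv(traits, path, progress = FALSE)
  if (!is.null(meta_path)) {
    if (is.null(meta)) stop("no trait metadata to write")
    readr::write_csv(meta, meta_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname read_community_matrix
#' @param cm Community tibble to write.
#' @export
write_community_matrix <- function(cm, path) {
  readr::write_csv(cm, path, progress = FALSE)
  invisible(path)
}

# --- internal tibble <-> matrix helpers ------------------------------------

trait_names <- function(traits) setdiff(names(traits), "species")

species_names <- function(cm) setdiff(names(cm), c("plot_id", "site_id", "depth_m"))

trait_matrix <- function(traits) {
  m <- as.matrix(traits[trait_names(traits)])
  rownames(m) <- traits$species
  storage.mode(m) <- "double"
  m
}

abundance_matrix <- function(cm) {
  m <- as.matrix(cm[species_names(cm)])
  rownames(m) <- cm$plot_id
  storage.mode(m) <- "double"
  m
}
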