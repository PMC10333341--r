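# ---- ROI registry ----------------------------------------------------------

#' Load and validate an ROI parcellation registry
#'
#' The registry enumerates the 111 regions of a Harvard-Oxford-style
#' parcellation: 48 cortical regions per hemisphere, 7 subcortical regions per
#' hemisphere, and the brainstem. Every downstream table (centrality,
#' hub tests, moderation, symptom-mixture fits) is indexed against it.
#'
#' @param path Path to a tab-separated registry file with header columns
#'   `index`, `name`, `hemisphere`, `abbreviation`, `category`. `index` must
#'   be the contiguous 0-based sequence 0..110; `hemisphere` is one of
#'   `left`, `right`, `midline`; `category` is one of `cortical`,
#'   `subcortical`, `brainstem`. Defaults to the bundled registry.
#' @return A `roi_registry` (a data frame with the columns above, validated).
#' @examples
#' reg <- load_registry()
#' nrow(reg)  # 111
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_registry(df)
}

default_registry_path <- function() {
  system.file("extdata", "roi_registry_ho111.tsv", package = "ecnet",
              mustWork = TRUE)
}

validate_registry <- function(df) {
  need <- c("index", "name", "hemisphere", "abbreviation", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) != 111L)
    stop("expected 111 regions, got ", nrow(df))
  if (anyDuplicated(df$index))
    stop("duplicate ROI index: ",
         paste(unique(df$index[duplicated(df$index)]), collapse = ", "))
  if (!identical(sort(as.integer(df$index)), 0:110))
    stop("ROI indices must be the contiguous 0-based sequence 0..110")
  bad_hemi <- !df$hemisphere %in% c("left", "right", "midline")
  if (any(bad_hemi))
    stop("invalid hemisphere in row(s): ", paste(which(bad_hemi), collapse = ", "))
  bad_cat <- !df$category %in% c("cortical", "subcortical", "brainstem")
  if (any(bad_cat))
    stop("invalid category in row(s): ", paste(which(bad_cat), collapse = ", "))
  counts <- c(
    sum(df$category == "cortical" & df$hemisphere == "left"),
    sum(df$category == "cortical" & df$hemisphere == "right"),
    sum(df$category == "subcortical" & df$hemisphere == "left"),
    sum(df$category == "subcortical" & df$hemisphere == "right"),
    sum(df$category == "brainstem"))
  if (!identical(counts, c(48L, 48L, 7L, 7L, 1L)))
    stop("region counts (Lcort, Rcort, Lsub, Rsub, brainstem) must be ",
         "48/48/7/7/1, got ", paste(counts, collapse = "/"))
  df <- df[order(df$index), , drop = FALSE]
  df$index <- as.integer(df$index)
  rownames(df) <- NULL
  class(df) <- c("roi_registry", "data.frame")
  df
}

#' Write a registry to a TSV file
#'
#' Round-trips bit-identically through [load_registry()].
#' @param registry A `roi_registry`.
#' @param path Output path.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(as.data.frame(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up one ROI by abbreviation and hemisphere
#'
#' @param registry A `roi_registry`.
#' @param abbreviation Short region code, e.g. `"PHG"`.
#' @param hemisphere `"left"`, `"right"` or `"midline"`.
#' @return The single matching registry row.
#' @export
roi_lookup <- function(registry, abbreviation, hemisphere) {
  hit <- registry$abbreviation == abbreviation &
    registry$hemisphere == hemisphere
  if (sum(hit) == 0L)
    stop("no ROI with abbreviation '", abbreviation, "' in hemisphere '",
         hemisphere, "'")
  if (sum(hit) > 1L)
    stop("ambiguous lookup: ", abbreviation, "/", hemisphere)
  registry[hit, , drop = FALSE]
}

#' Subset a registry to named regions
#'
#' Original 0-based indices are preserved so the subset can still address
#' columns of a full 111-column table. Identifiers may be full names,
#' or `"ABBR/hemisphere"` strings (e.g. `"PHG/right"`).
#'
#' @param registry A `roi_registry`.
#' @param names Character vector of identifiers, or an integer vector of
#'   0-based ROI indices.
#' @return A `roi_registry` subset (class kept; length-111 invariants not
#'   re-enforced).
#' @export
hub_subset <- function(registry, names) {
  if (length(names) == 0L) {
    out <- registry[0L, , drop = FALSE]
    class(out) <- class(registry)
    return(out)
  }
  if (is.numeric(names)) {
    idx <- as.integer(names)
    bad <- !idx %in% registry$index
    if (any(bad)) stop("unknown ROI index: ", paste(idx[bad], collapse = ", "))
    rows <- match(idx, registry$index)
  } else {
    rows <- vapply(names, function(nm) {
      if (grepl("/", nm, fixed = TRUE)) {
        parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
        hit <- which(registry$abbreviation == parts[1L] &
                       registry$hemisphere == parts[2L])
      } else {
        hit <- which(registry$name == nm)
      }
      if (length(hit) == 0L) stop("unknown ROI identifier: '", nm, "'")
      if (length(hit) > 1L) stop("ambiguous ROI identifier: '", nm,
                                 "' (qualify as ABBR/hemisphere)")
      hit
    }, integer(1))
  }
  if (anyDuplicated(rows)) {
    warning("duplicate ROI identifiers collapsed to single entries")
    rows <- unique(rows)
  }
  out <- registry[rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(registry)
  out
}

#' Default hub set: the nine regions used throughout the worked examples
#'
#' Right anterior inferior temporal gyrus, right superior parietal lobule,
#' right anterior parahippocampal gyrus, right anterior and posterior
#' temporal fusiform cortex, right caudate, brainstem, left anterior
#' inferior temporal gyrus and left amygdala.
#'
#' @return Integer vector of nine 0-based ROI indices into the bundled
#'   registry.
#' @export
default_hub_rois <- function() {
  c(61L, 65L, 81L, 84L, 85L, 104L, 110L, 13L, 101L)
}

#' @export
print.roi_registry <- function(x, ...) {
  cat("ROI registry:", nrow(x), "regions (",
      sum(x$category == "cortical"), "cortical,",
      sum(x$category == "subcortical"), "subcortical,",
      sum(x$category == "brainstem"), "brainstem )\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
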