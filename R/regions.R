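#' Canonical cortical region sets
#'
#' A region set fixes the node identity and node order of every network in the
#' pipeline: one node per cortical parcel, left-hemisphere parcels first, each
#' hemisphere alphabetical. The packaged default is the 68-parcel
#' Desikan-Killiany gyral atlas (34 parcels per hemisphere), the standard
#' FreeSurfer `aparc` parcellation.
#'
#' @param regions data.frame with columns `name` and `hemisphere`
#'   (`"left"`/`"right"`, abbreviations `l`/`lh`/`r`/`rh` accepted).
#' @return An object of class `region_set`: a data.frame with columns
#'   `name`, `hemisphere` and `id` (`lh_<name>` / `rh_<name>`), ordered
#'   left-then-right, alphabetical within hemisphere.
#' @export
region_set <- function(regions) {
  stopifnot(is.data.frame(regions), all(c("name", "hemisphere") %in% names(regions)))
  hemi <- tolower(trimws(as.character(regions$hemisphere)))
  hemi[hemi %in% c("l", "lh", "left")] <- "left"
  hemi[hemi %in% c("r", "rh", "right")] <- "right"
  bad <- setdiff(unique(hemi), c("left", "right"))
  if (length(bad) > 0) {
    stop("unknown hemisphere code(s): ", paste(bad, collapse = ", "))
  }
  name <- trimws(as.character(regions$name))
  key <- paste(hemi, name)
  if (anyDuplicated(key)) {
    stop("duplicate region name(s): ",
         paste(unique(name[duplicated(key)]), collapse = ", "))
  }
  out <- data.frame(name = name, hemisphere = hemi, stringsAsFactors = FALSE)
  out <- out[order(match(out$hemisphere, c("left", "right")), out$name), ]
  rownames(out) <- NULL
  out$id <- paste0(ifelse(out$hemisphere == "left", "lh_", "rh_"), out$name)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Load a region table from a two-column TSV
#'
#' @param path path to a TSV with columns `name` and `hemisphere`; if missing,
#'   the packaged Desikan-Killiany 68-region table is used.
#' @return a [region_set()]
#' @export
load_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "desikan68_regions.tsv", package = "scnets")
  }
  if (!file.exists(path)) stop("region table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_set(tab)
}

#' The packaged Desikan-Killiany 68-region set
#' @return a [region_set()] of 68 cortical parcels
#' @export
desikan_regions <- function() load_region_table(NULL)

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", nrow(x), " regions (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  invisible(x)
}
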