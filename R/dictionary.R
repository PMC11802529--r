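#' Two-level PT-to-SOC dictionary
#'
#' A minimal MedDRA-style terminology: each preferred term (PT) maps to
#' exactly one System Organ Class (SOC). Lookups of unknown PTs are an error,
#' never a silent default, so coding mistakes surface at aggregation time.
#'
#' @param pt Character vector of preferred term names (unique, non-empty).
#' @param soc Character vector of SOC names, same length as `pt`.
#' @return A tibble of class `meddra_dict` with columns `pt` and `soc`.
#' @export
#' @examples
#' d <- meddra_dictionary(c("Nausea", "Headache"),
#'                        c("Gastrointestinal disorders", "Nervous system disorders"))
#' soc_of(d, "Nausea")
meddra_dictionary <- function(pt, soc) {
  pt <- as.character(pt)
  soc <- as.character(soc)
  if (length(pt) == 0) abort("dictionary must contain at least one PT")
  if (length(pt) != length(soc)) abort("`pt` and `soc` must have equal length")
  if (anyNA(pt) || anyNA(soc) || any(pt == "") || any(soc == "")) {
    abort("dictionary entries must be non-missing, non-empty strings")
  }
  if (anyDuplicated(pt)) {
    abort(paste0("duplicated PT in dictionary: ",
                 paste(unique(pt[duplicated(pt)]), collapse = ", ")))
  }
  structure(tibble::tibble(pt = pt, soc = soc),
            class = c("meddra_dict", class(tibble::tibble())))
}

#' Look up the SOC of one or more PTs
#'
#' @param dict A [meddra_dictionary()].
#' @param pt Character vector of PT names to resolve.
#' @return Character vector of SOC names, same length as `pt`.
#' @export
soc_of <- function(dict, pt) {
  stopifnot(inherits(dict, "meddra_dict"))
  idx <- match(pt, dict$pt)
  if (anyNA(idx)) {
    abort(paste0("unknown PT(s): ", paste(unique(pt[is.na(idx)]), collapse = ", ")))
  }
  dict$soc[idx]
}

#' Read / write a dictionary as two-column CSV (`pt,soc`)
#'
#' @param path File path.
#' @return `read_meddra_dictionary()` returns a `meddra_dict`;
#'   `write_meddra_dictionary()` returns `path` invisibly.
#' @export
read_meddra_dictionary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("pt", "soc"), names(df))
  if (length(missing)) {
    abort(paste0("dictionary file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  meddra_dictionary(df$pt, df$soc)
}

#' @rdname read_meddra_dictionary
#' @param dict A `meddra_dict` to serialize.
#' @export
write_meddra_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "meddra_dict"))
  readr::write_csv(tibble::as_tibble(dict), path)
  invisible(path)
}
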