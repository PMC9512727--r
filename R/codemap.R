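#' Default claims code map
#'
#' The published code lists behind the study design live in supplementary
#' material that is not redistributable, so the package ships a miniature,
#' self-contained map of ICD-10-GM-like diagnosis prefixes and OPS-like
#' procedure prefixes.  It is a configuration artifact: every function that
#' interprets codes takes the map as an argument, and a different map can be
#' supplied from YAML via [read_code_map()].
#'
#' `fracture_sites` is an *ordered* list: a diagnosis code is assigned to the
#' first site whose prefix matches, so codes that could map to several sites
#' (e.g. `S32.*`) resolve deterministically.
#'
#' @return A list with elements `fracture_sites` (ordered list of character
#'   prefix vectors, one per site), `exclusions` (prefixes for cancer,
#'   Paget's disease and osteogenesis imperfecta), `fracture_procedures`
#'   (OPS-like prefixes of fracture-related procedures),
#'   `hysterectomy_procedures`, `drug_classes` and `hierarchy` (the
#'   treatment-assignment priority tiers).
#' @export
default_code_map <- function() {
  list(
    fracture_sites = list(
      clinical_vertebral = c("S12", "S22.0", "S22.1", "S32.0", "M80"),
      hip = c("S72.0", "S72.1", "S72.2"),
      wrist_forearm = c("S52"),
      humerus = c("S42.2", "S42.3", "S42.4"),
      clavicle = c("S42.0"),
      pelvis = c("S32.1", "S32.3", "S32.4", "S32.5", "S32.8"),
      femur = c("S72.3", "S72.4", "S72.8", "S72.9")
    ),
    exclusions = list(
      cancer = "C",
      paget = "M88",
      osteogenesis_imperfecta = "Q78.0"
    ),
    fracture_procedures = c("5-78", "5-79", "5-82", "8-200"),
    hysterectomy_procedures = c("5-683"),
    drug_classes = c(
      "denosumab", "iv_ibandronate", "iv_zoledronate",
      "oral_bisphosphonate", "teriparatide", "raloxifene", "hrt"
    ),
    hierarchy = list(
      "denosumab",
      c("iv_ibandronate", "iv_zoledronate"),
      "oral_bisphosphonate",
      "teriparatide",
      "raloxifene",
      "hrt"
    )
  )
}

#' Read / write a code map as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_code_map()` returns the code-map list; `write_code_map()`
#'   returns `path` invisibly.
#' @export
read_code_map <- function(path) {
  map <- yaml::read_yaml(path)
  needed <- c("fracture_sites", "exclusions", "fracture_procedures",
              "hysterectomy_procedures", "drug_classes", "hierarchy")
  missing <- setdiff(needed, names(map))
  if (length(missing))
    stop("code map is missing elements: ", paste(missing, collapse = ", "))
  map
}

#' @rdname read_code_map
#' @param map A code-map list as returned by [default_code_map()].
#' @export
write_code_map <- function(map, path) {
  yaml::write_yaml(map, path)
  invisible(path)
}

#' Assign fracture sites to diagnosis codes
#'
#' Vectorised first-prefix-match lookup over the ordered site list.
#'
#' @param codes Character vector of diagnosis codes.
#' @param map Code map (see [default_code_map()]).
#' @return Character vector of site names, `NA` where no prefix matches.
#' @export
classify_site <- function(codes, map = default_code_map()) {
  out <- rep(NA_character_, length(codes))
  for (site in names(map$fracture_sites)) {
    hit <- startswith_any(codes, map$fracture_sites[[site]]) & is.na(out)
    out[hit] <- site
  }
  out
}

is_exclusion_code <- function(codes, map = default_code_map()) {
  startswith_any(codes, unlist(map$exclusions, use.names = FALSE))
}

startswith_any <- function(x, prefixes) {
  hit <- rep(FALSE, length(x))
  for (p in prefixes) hit <- hit | startsWith(x, p)
  hit
}
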