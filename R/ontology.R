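#' @importFrom utils read.table write.table
NULL

.divisions <- c("isocortex", "cortical plate", "cortical subplate",
                "striatum", "pallidum", "thalamus", "hypothalamus",
                "midbrain", "pons", "medulla")

#' Construct a region ontology
#'
#' A region ontology is the fixed catalogue of atlas summary structures that
#' every matrix in the pipeline is indexed by: one row per region, with a
#' unique acronym, a free-text name, the major anatomical division, and the
#' structure volume in cubic millimetres. Row order is preserved and defines
#' the region order of all downstream count, density, correlation and
#' adjacency matrices.
#'
#' @param regions data.frame with columns `acronym`, `name`, `division`,
#'   `volume_mm3` (a bare `volume` column is accepted and renamed).
#' @return An object of class `region_ontology` (a validated data.frame).
#' @export
region_ontology <- function(regions) {
  stopifnot(is.data.frame(regions))
  names(regions)[names(regions) == "volume"] <- "volume_mm3"
  need <- c("acronym", "name", "division", "volume_mm3")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("region table is missing column(s): ", paste(miss, collapse = ", "))
  regions <- regions[, need]
  regions$acronym <- as.character(regions$acronym)
  regions$name <- as.character(regions$name)
  regions$division <- as.character(regions$division)
  regions$volume_mm3 <- as.numeric(regions$volume_mm3)
  dup <- unique(regions$acronym[duplicated(regions$acronym)])
  if (length(dup))
    stop("duplicate region acronym(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(regions$division), .divisions)
  if (length(bad))
    stop("unknown major division(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(.divisions, collapse = ", "), ")")
  if (any(!is.finite(regions$volume_mm3)) || any(regions$volume_mm3 <= 0))
    stop("all region volumes must be finite and > 0; offending acronym(s): ",
         paste(regions$acronym[!is.finite(regions$volume_mm3) |
                                 regions$volume_mm3 <= 0], collapse = ", "))
  rownames(regions) <- NULL
  class(regions) <- c("region_ontology", "data.frame")
  regions
}

#' Load a region table from a delimited file
#'
#' Reads a TSV or CSV region catalogue (header required, columns
#' `acronym,name,division,volume_mm3`) and validates it into a
#' [region_ontology]. The delimiter is sniffed from the header line.
#'
#' @param path path to the delimited file.
#' @param expected_count optional integer; error if the table size differs.
#' @return A `region_ontology`.
#' @examples
#' ont <- load_region_table(default_region_table(), expected_count = 196)
#' nrow(ont)
#' @export
load_region_table <- function(path, expected_count = NULL) {
  df <- .read_delim_auto(path)
  ont <- region_ontology(df)
  if (!is.null(expected_count) && nrow(ont) != expected_count)
    stop("region table has ", nrow(ont), " regions, expected ",
         expected_count)
  ont
}

#' Write a region ontology to TSV
#' @param ontology a `region_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(ontology, path) {
  stopifnot(inherits(ontology, "region_ontology"))
  write.table(ontology, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to the shipped synthetic 196-region catalogue
#'
#' The package ships a synthetic catalogue of 196 Allen-atlas-style summary
#' structures spanning isocortex, cortical plate, cortical subplate,
#' striatum, pallidum, thalamus, hypothalamus, midbrain, pons and medulla.
#' Acronyms are the field's conventional ones (all regions named in the
#' shipped functional-network definitions are present); volumes are
#' synthetic placeholders, not measured atlas volumes.
#'
#' @return File path to the TSV.
#' @export
default_region_table <- function() {
  system.file("extdata", "synthetic_regions_196.tsv", package = "cofosnet",
              mustWork = TRUE)
}

#' Load functional-network definitions
#'
#' Functional networks (social, salience, default-mode, lateral-cortical)
#' are fixed sets of region acronyms; they are data, not code, so users can
#' redefine them. Accepts YAML (`network_name: [acronyms]`) or long-format
#' TSV (columns `network,acronym`). Every member must resolve in the
#' ontology; a region may belong to several networks.
#'
#' @param path YAML or TSV file.
#' @param ontology the `region_ontology` the members must resolve in.
#' @return Named list of character vectors, class `network_definitions`.
#' @examples
#' ont <- load_region_table(default_region_table())
#' nets <- load_network_definitions(default_network_definitions(), ont)
#' lengths(nets)
#' @export
load_network_definitions <- function(path, ontology) {
  stopifnot(inherits(ontology, "region_ontology"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    defs <- yaml::read_yaml(path)
    defs <- lapply(defs, as.character)
  } else {
    df <- .read_delim_auto(path)
    if (!all(c("network", "acronym") %in% names(df)))
      stop("TSV network definitions need columns `network` and `acronym`")
    defs <- split(as.character(df$acronym), df$network)
  }
  if (is.null(names(defs)) || any(!nzchar(names(defs))))
    stop("every network must be named")
  for (nm in names(defs)) {
    unknown <- setdiff(defs[[nm]], ontology$acronym)
    if (length(unknown))
      stop("network '", nm, "' names region(s) absent from the ontology: ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(defs[[nm]]))
      stop("network '", nm, "' lists duplicate members")
  }
  structure(defs, class = "network_definitions")
}

#' Path to the shipped functional-network definition file
#'
#' The four canonical networks as fixed acronym lists: salience (AI, BLA,
#' CEA, MEA, MED, DR, CLA), social (HPF, ACA, PL, VTA, MD, ACB, MPO, MEA,
#' CEA, BLA), default_mode (STRd, VISp, BMA, LAT, ZI, CS, ACA, PL, HPF,
#' MEA) and lateral_cortical (MOp, SSp, VPM, ACA).
#'
#' @return File path to the YAML.
#' @export
default_network_definitions <- function() {
  system.file("extdata", "functional_networks.yaml", package = "cofosnet",
              mustWork = TRUE)
}

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, quote = "\"",
             comment.char = "", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @export
print.region_ontology <- function(x, ...) {
  cat("Region ontology:", nrow(x), "regions across",
      length(unique(x$division)), "major divisions\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... and", nrow(x) - 4, "more rows\n")
  invisible(x)
}
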