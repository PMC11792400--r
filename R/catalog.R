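#' CAZyme functional-group catalog
#'
#' The catalog assigns CAZyme families (with subfamily suffixes, e.g.
#' `GH5-1`) to the functional groups used throughout the package:
#'
#' * `cellulase` -- endo/exo-cellulases and lytic polysaccharide
#'   monooxygenases attacking the cellulose backbone;
#' * `xylanase` -- xylan backbone hydrolases;
#' * `ligninolytic` -- laccases and class II peroxidases;
#' * `oh_pbh` -- oligosaccharide hydrolases (OHs) and
#'   polysaccharide-branch hydrolases (PBHs), the enzymes that consume
#'   decomposition products rather than the polymer backbone.
#'
#' Any family with a `GT` prefix is a glycosyltransferase and is excluded
#' from all degradative statistics; families not listed in the catalog are
#' classified `other`.
#'
#' The same catalog is shipped as a plain TSV resource
#' (`system.file("extdata", "cazyme_groups.tsv", package = "decomplex")`)
#' for use outside R.
#'
#' @return A list with character vectors `cellulase`, `xylanase`,
#'   `ligninolytic`, and `oh_pbh`.
#' @examples
#' cat <- cazyme_catalog()
#' length(cat$cellulase)
#' @export
cazyme_catalog <- function() {
  list(
    cellulase = c(
      "GH5-1", "GH5-2", "GH5-22", "GH5-25", "GH5-26", "GH5-37", "GH5-38",
      "GH5-4", "GH5-46", "GH5-5", "GH5-52", "GH5-53", "GH5-55", "GH6",
      "GH7", "GH8", "GH9", "GH12", "GH44", "GH45", "GH48", "GH74",
      "GH124", "GH131", "AA9", "AA10", "AA3-1", "AA15", "AA16"
    ),
    xylanase = c(
      "GH5-21", "GH5-34", "GH5-35", "GH10", "GH11", "GH30-7", "GH30-8",
      "AA14", "GH43-17", "GH43-7"
    ),
    ligninolytic = c("AA1-1", "AA1-2", "AA1-3", "AA2"),
    oh_pbh = c(
      "GH1", "GH2", "GH3", "GH116", "GH39", "GH40", "GH43-1", "GH43-10",
      "GH43-11", "GH43-12", "GH43-14", "GH43-16", "GH43-18", "GH43-19",
      "GH43-2", "GH43-20", "GH43-21", "GH43-22", "GH43-23", "GH43-26",
      "GH43-27", "GH43-29", "GH43-30", "GH43-32", "GH43-33", "GH43-34",
      "GH43-35", "GH43-36", "GH43-37", "GH43-4", "GH43-5", "GH43-9",
      "GH5-43", "GH5-45", "CE1", "CE2", "CE3", "CE4", "CE5", "CE6",
      "CE7", "CE12", "CE16", "GH5-9", "GH95", "GH62", "GH67", "GH52",
      "GH54", "GH120"
    )
  )
}

#' Normalize CAZyme family identifiers
#'
#' Family names are upper-cased and the underscore subfamily dialect
#' (`GH5_1`) is converted to the hyphen form (`GH5-1`). Malformed names
#' (anything not matching `<CLASS><number>[-<number>]`) raise an error.
#'
#' @param family Character vector of family identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_family(c("gh5_1", "GT2"))
#' @export
normalize_family <- function(family) {
  if (!is.character(family)) {
    stop("`family` must be a character vector", call. = FALSE)
  }
  x <- toupper(trimws(family))
  x <- gsub("_", "-", x, fixed = TRUE)
  ok <- grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+(-[0-9]+)?$", x)
  if (any(!ok)) {
    stop(
      "malformed CAZyme family name(s): ",
      paste(unique(family[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Classify CAZyme families into functional groups
#'
#' Deterministic lookup against [cazyme_catalog()]: families with a `GT`
#' prefix map to `gt`, listed families map to their group, and anything
#' else maps to `other`.
#'
#' @param family Character vector of family identifiers (normalized on
#'   input; the underscore dialect is accepted).
#' @param catalog Catalog list as returned by [cazyme_catalog()].
#' @return Character vector over
#'   `{cellulase, xylanase, ligninolytic, oh_pbh, gt, other}`.
#' @examples
#' classify_family(c("GH7", "GH10", "GT2", "CBM50"))
#' @export
classify_family <- function(family, catalog = cazyme_catalog()) {
  x <- normalize_family(family)
  out <- rep("other", length(x))
  out[startsWith(x, "GT")] <- "gt"
  for (grp in names(catalog)) {
    out[x %in% catalog[[grp]]] <- grp
  }
  out
}

#' Write the functional-group catalog as TSV
#'
#' @param path Output file path.
#' @param catalog Catalog list as returned by [cazyme_catalog()].
#' @return The path, invisibly.
#' @export
write_catalog_tsv <- function(path, catalog = cazyme_catalog()) {
  df <- data.frame(
    family = unlist(catalog, use.names = FALSE),
    group = rep(names(catalog), lengths(catalog)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional-group catalog from TSV
#'
#' @param path TSV file with columns `family` and `group`.
#' @return A catalog list in the shape of [cazyme_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "group") %in% names(df)))
  split(normalize_family(df$family), df$group)[
    c("cellulase", "xylanase", "ligninolytic", "oh_pbh")
  ]
}
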