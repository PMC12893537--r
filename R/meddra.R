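# PT -> SOC vocabulary and drug dictionaries. MedDRA itself is licensed and
# not bundled; the vocabulary arrives as a simple two-column map (a toy one
# ships under inst/extdata). Each PT maps to exactly one SOC (primary-SOC
# convention), so SOC-level rollups partition events.

#' Load a PT-to-SOC vocabulary map
#'
#' Reads a two-column tab-separated file (`pt`, `soc`; an optional header
#' line with those names is skipped). Duplicate PT lines that agree are
#' collapsed; conflicting duplicates are an error naming the offending PTs.
#'
#' @param path Path to the tab-separated file.
#' @return A `meddra_vocab` object: named vector `pt_to_soc` plus
#'   `soc_list` in file order.
#' @export
load_vocabulary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("pt", "soc"),
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) pv_stop("empty vocabulary file", "pv_format_error")
  if (trimlower(df$pt[1]) == "pt" && trimlower(df$soc[1]) == "soc") {
    df <- df[-1L, , drop = FALSE]
  }
  pt <- trimlower(df$pt)
  soc <- trimws(df$soc)
  dup <- !duplicated(paste(pt, soc))
  pt <- pt[dup]; soc <- soc[dup]
  conflicts <- unique(pt[duplicated(pt)])
  if (length(conflicts)) {
    pv_stop(sprintf("PT(s) mapped to more than one SOC: %s",
                    paste(conflicts, collapse = ", ")), "pv_format_error")
  }
  structure(list(pt_to_soc = stats::setNames(soc, pt),
                 soc_list = unique(soc)),
            class = "meddra_vocab")
}

#' @export
print.meddra_vocab <- function(x, ...) {
  cat(sprintf("<meddra_vocab> %d PT(s) across %d SOC(s)\n",
              length(x$pt_to_soc), length(x$soc_list)))
  invisible(x)
}

#' Map preferred terms to their system organ class
#'
#' @param vocab A `meddra_vocab` object.
#' @param pts Character vector of PTs (case-insensitive).
#' @return SOC names; PTs absent from the vocabulary return `"unmapped"`
#'   so the pipeline can proceed and report coverage rather than fail.
#' @export
map_pt_to_soc <- function(vocab, pts) {
  stopifnot(inherits(vocab, "meddra_vocab"))
  map_with_default(trimlower(pts), vocab$pt_to_soc, "unmapped")
}

#' Load a drug dictionary
#'
#' Reads a three-column tab-separated file (`alias`, `standard`, `class`;
#' optional header). Classes must be one of `heparin_lmwh`, `warfarin`,
#' `doac`, `other_anticoagulant`, `antiplatelet`, `none`. Every standard
#' name is also registered as an alias of itself, which makes
#' normalization idempotent.
#'
#' @param path Path to the tab-separated file.
#' @return A `drug_dictionary` object.
#' @export
load_drug_dictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("alias", "standard", "class"),
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) pv_stop("empty drug dictionary", "pv_format_error")
  if (trimlower(df$alias[1]) == "alias") df <- df[-1L, , drop = FALSE]
  alias <- trimlower(df$alias)
  standard <- trimlower(df$standard)
  class <- trimlower(df$class)
  bad <- setdiff(unique(class), drug_class_levels)
  if (length(bad)) {
    pv_stop(sprintf("unknown drug class(es): %s", paste(bad, collapse = ", ")),
            "pv_format_error")
  }
  # self-aliases for the standard names
  extra <- !(standard %in% alias)
  alias <- c(alias, standard[extra])
  std_all <- c(standard, standard[extra])
  keep <- !duplicated(alias)
  alias_to_standard <- stats::setNames(std_all[keep], alias[keep])
  cls_keep <- !duplicated(standard)
  class_of <- stats::setNames(class[cls_keep], standard[cls_keep])
  structure(list(alias_to_standard = alias_to_standard, class_of = class_of),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat(sprintf("<drug_dictionary> %d alias(es) -> %d standard name(s)\n",
              length(x$alias_to_standard), length(x$class_of)))
  invisible(x)
}

#' Standardize a drug name and look up its class
#'
#' Lookup is case-insensitive after trimming. Unknown names pass through
#' lower-cased with class `"none"`; normalization is a fixed point
#' (classifying an already-standard name returns it unchanged).
#'
#' @param dict A `drug_dictionary` object.
#' @param name_raw Character vector of drug names as reported.
#' @return Data frame with columns `name_standard` and `class`.
#' @export
classify_drug <- function(dict, name_raw) {
  stopifnot(inherits(dict, "drug_dictionary"))
  key <- trimlower(name_raw)
  std <- unname(dict$alias_to_standard[key])
  std[is.na(std)] <- key[is.na(std)]
  cls <- map_with_default(std, dict$class_of, "none")
  data.frame(name_standard = std, class = cls, stringsAsFactors = FALSE)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
pv_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "pvsignal")))
  }
  system.file("extdata", file, package = "pvsignal", mustWork = TRUE)
}
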