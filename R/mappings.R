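#' Load a diagnosis code mapping
#'
#' Loads a CSV mapping diagnosis codes to category labels, used both for
#' clinical condition grouping (CCS-style reporting categories, `kind =
#' "ccs"`) and for the Quan adaptation of the Charlson comorbidity
#' categories with their weights (`kind = "quan"`).
#'
#' The file has columns `code,category` (`ccs`) or `code,category,weight`
#' (`quan`). A code ending in `*` is a prefix entry and matches every code
#' starting with that prefix; exact entries take precedence over prefix
#' entries, and among prefix entries the longest matching prefix wins.
#' Diagnosis codes are treated as opaque strings: no ICD revision is
#' hard-coded, so ICD-9-CM and ICD-10 cohorts are both supported by
#' supplying the corresponding mapping file.
#'
#' For `kind = "quan"` the mapping carries, as attributes, the category
#' weight table and the three mild/severe hierarchy pairs (liver disease;
#' diabetes without/with chronic complication; malignancy/metastatic solid
#' tumour) used by [compute_ccmi()]. Hierarchy pairs are matched by the
#' canonical category labels shipped in the packaged weight file; a custom
#' quan mapping must reuse those labels for the paired categories.
#'
#' Small example files ship with the package, see
#' `system.file("extdata", "quan_ccmi_toy.csv", package = "husegment")` and
#' `"ccs_toy.csv"`; they are illustrative subsets, not the full published
#' crosswalks.
#'
#' @param path Path to the mapping CSV.
#' @param kind `"ccs"` or `"quan"`.
#' @return An object of class `code_mapping`.
#' @export
load_code_mapping <- function(path, kind = c("ccs", "quan")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_husegment("mapping file does not exist: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  if (!all(c("code", "category") %in% names(raw))) {
    stop_husegment("mapping file must have columns code,category",
                   if (kind == "quan") ",weight")
  }
  if (kind == "quan" && !("weight" %in% names(raw))) {
    stop_husegment("quan mapping file must have a weight column")
  }
  code <- raw$code
  is_prefix <- endsWith(code, "*")
  exact <- raw[!is_prefix, , drop = FALSE]
  dup <- duplicated(exact$code)
  if (any(dup)) {
    conflicted <- unique(exact$code[dup])
    conflict <- vapply(conflicted, function(cd) {
      length(unique(exact$category[exact$code == cd])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop_husegment("duplicate exact code(s) with conflicting category: ",
                     paste(conflicted[conflict], collapse = ", "))
    }
    exact <- exact[!dup, , drop = FALSE]
  }
  prefix <- raw[is_prefix, , drop = FALSE]
  prefix$code <- sub("\\*$", "", prefix$code)
  prefix <- prefix[order(-nchar(prefix$code), prefix$code), , drop = FALSE]
  exact_map <- stats::setNames(exact$category, exact$code)

  weights <- NULL
  if (kind == "quan") {
    w <- suppressWarnings(as.numeric(raw$weight))
    if (anyNA(w)) stop_husegment("non-numeric weight(s) in quan mapping")
    cats <- unique(raw$category)
    weights <- vapply(cats, function(cc) {
      ww <- unique(w[raw$category == cc])
      if (length(ww) > 1L) {
        stop_husegment("category '", cc, "' has conflicting weights")
      }
      ww
    }, numeric(1))
    pairs <- quan_hierarchy_pairs()
    in_pairs <- table(c(pairs))
    if (any(in_pairs > 1L)) {
      stop_husegment("a category appears in more than one hierarchy pair")
    }
  }
  structure(
    list(exact = exact_map,
         prefix = data.frame(prefix = prefix$code, category = prefix$category,
                             stringsAsFactors = FALSE),
         weights = weights,
         kind = kind),
    class = "code_mapping",
    hierarchy = if (kind == "quan") quan_hierarchy_pairs() else NULL
  )
}

#' Mild/severe hierarchy pairs of the Charlson categories
#'
#' Within each pair, only the severe member contributes to the comorbidity
#' index when both are present for a patient. Rows are `c(mild, severe)`.
#'
#' @return A 3 x 2 character matrix with columns `mild`, `severe`.
#' @export
quan_hierarchy_pairs <- function() {
  matrix(c(
    "Mild liver disease", "Moderate or severe liver disease",
    "Diabetes without chronic complication", "Diabetes with chronic complication",
    "Any malignancy", "Metastatic solid tumour"
  ), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("mild", "severe")))
}

#' Map diagnosis codes to categories
#'
#' Vectorized lookup: exact entries first, then the longest matching prefix
#' entry; unmatched codes return `NA`.
#'
#' @param codes Character vector of diagnosis codes.
#' @param mapping A `code_mapping` from [load_code_mapping()].
#' @return Character vector of category labels (`NA` where unmapped).
#' @export
map_code <- function(codes, mapping) {
  stopifnot(inherits(mapping, "code_mapping"))
  codes <- as.character(codes)
  out <- unname(mapping$exact[codes])
  todo <- is.na(out) & !is.na(codes)
  if (any(todo) && nrow(mapping$prefix)) {
    for (i in seq_len(nrow(mapping$prefix))) {
      if (!any(todo)) break
      hit <- todo & startsWith(codes, mapping$prefix$prefix[i])
      out[hit] <- mapping$prefix$category[i]
      todo <- todo & !hit
    }
  }
  out
}

#' @export
print.code_mapping <- function(x, ...) {
  cat(sprintf("<code_mapping kind=%s: %d exact, %d prefix entries", x$kind,
              length(x$exact), nrow(x$prefix)))
  if (!is.null(x$weights)) {
    cat(sprintf(", %d weighted categories", length(x$weights)))
  }
  cat(">\n")
  invisible(x)
}
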