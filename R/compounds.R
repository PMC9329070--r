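#' Classify a PAH by molecular-weight class
#'
#' PAHs with four or more fused aromatic rings are conventionally grouped as
#' high-molecular-weight (HMW); two- and three-ring compounds are
#' low-molecular-weight (LMW). This split tracks hydrophobicity and therefore
#' the partitioning behaviour modelled by [bcf()].
#'
#' @param n_rings Integer vector of fused aromatic ring counts (each >= 2).
#' @return Character vector, `"LMW"` or `"HMW"`.
#' @examples
#' classify_weight_class(c(3, 4, 6))
#' @export
classify_weight_class <- function(n_rings) {
  if (length(n_rings) == 0L) return(character(0))
  if (!is.numeric(n_rings) || any(!is.finite(n_rings)) ||
      any(n_rings != round(n_rings))) {
    stop("n_rings must be whole numbers", call. = FALSE)
  }
  if (any(n_rings < 2)) {
    stop("invalid PAH structure: a PAH has at least 2 fused rings",
         call. = FALSE)
  }
  ifelse(n_rings >= 4, "HMW", "LMW")
}

# Volatile two/three-ring PAHs that standard C18/GC-MS workflows cannot
# quantify reliably; representable but excluded from default analyses.
VOLATILE_PAHS <- c("naphthalene", "acenaphthene", "acenaphthylene")

new_pah_registry <- function(df) {
  df$weight_class <- classify_weight_class(df$n_rings)
  df$volatile_excluded <- tolower(trimws(df$name)) %in% VOLATILE_PAHS
  rownames(df) <- NULL
  class(df) <- c("pah_registry", "data.frame")
  df
}

#' Load a PAH property registry from a CSV file
#'
#' The file must have columns `name,n_rings,log_kow,mw` (`#` lines are
#' comments). The molecular-weight class is derived from the ring count.
#' Volatile PAHs (naphthalene, acenaphthene, acenaphthylene) are accepted but
#' flagged `volatile_excluded`; with `strict = TRUE` (default) they are
#' excluded from the returned registry's active rows only by downstream
#' defaults, never silently dropped here.
#'
#' @param path Path to a property CSV.
#' @param strict Flag volatile compounds (default `TRUE`). With
#'   `strict = FALSE` the `volatile_excluded` column is all `FALSE`.
#' @return A `pah_registry` data frame with columns `name`, `n_rings`,
#'   `log_kow`, `mw`, `weight_class`, `volatile_excluded`.
#' @seealso [pah_registry()] for the shipped default table.
#' @export
load_compound_registry <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such property file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("name", "n_rings", "log_kow", "mw"),
                       "compound property table")
  df$name <- trimws(as.character(df$name))
  for (col in c("n_rings", "log_kow", "mw")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
    if (any(!is.finite(df[[col]]))) {
      stop(sprintf("column '%s' contains non-finite values", col),
           call. = FALSE)
    }
  }
  if (anyDuplicated(tolower(df$name))) {
    dup <- df$name[duplicated(tolower(df$name))]
    stop("duplicate compound name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$mw <= 0)) stop("mw must be > 0", call. = FALSE)
  reg <- new_pah_registry(df)
  if (!strict) reg$volatile_excluded[] <- FALSE
  reg
}

#' Default registry of the 13 quantified PAHs
#'
#' Fluorene, anthracene and phenanthrene (LMW) plus ten four-to-six-ring HMW
#' compounds, with literature log Kow and molecular weights from the shipped
#' property table (`system.file("extdata", "pah_properties.csv")`). The exact
#' log Kow values are configurable defaults; every downstream result depends
#' on them monotonically.
#'
#' @return A `pah_registry` data frame (see [load_compound_registry()]).
#' @examples
#' reg <- pah_registry()
#' table(reg$weight_class)
#' @export
pah_registry <- function() {
  load_compound_registry(
    system.file("extdata", "pah_properties.csv", package = "pahfate",
                mustWork = TRUE))
}
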