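#' Predictor variants
#'
#' A model variant switches groups of risk factors on or off on top of the
#' age-dependent baseline. The null variant (all flags off) predicts from age
#' alone; the full variant uses gene, PRS, questionnaire risk factors and
#' family history jointly.
#'
#' @param name variant label, unique within a run.
#' @param use_gene,use_prs,use_qrf,use_fh logical flags.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(name, use_gene = FALSE, use_prs = FALSE,
                          use_qrf = FALSE, use_fh = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name,
                 use_gene = isTRUE(use_gene), use_prs = isTRUE(use_prs),
                 use_qrf = isTRUE(use_qrf), use_fh = isTRUE(use_fh)),
            class = "model_variant")
}

#' @describeIn model_variant the standard ladder of nested variants:
#'   null (age only), PV, PV+QRF, PV+PRS, PV+QRF+PRS and the full
#'   PV+QRF+PRS+FH model.
#' @export
default_variants <- function() {
  list(
    model_variant("null"),
    model_variant("PV", use_gene = TRUE),
    model_variant("PV+QRF", use_gene = TRUE, use_qrf = TRUE),
    model_variant("PV+PRS", use_gene = TRUE, use_prs = TRUE),
    model_variant("PV+QRF+PRS", use_gene = TRUE, use_qrf = TRUE, use_prs = TRUE),
    model_variant("PV+QRF+PRS+FH", use_gene = TRUE, use_qrf = TRUE,
                  use_prs = TRUE, use_fh = TRUE)
  )
}

.check_variants <- function(variants) {
  if (inherits(variants, "model_variant")) variants <- list(variants)
  if (!length(variants)) stop("at least one model variant is required")
  nm <- vapply(variants, function(v) v$name, character(1))
  if (anyDuplicated(nm)) stop("variant names must be unique")
  names(variants) <- nm
  variants
}

#' @export
print.model_variant <- function(x, ...) {
  on <- c("gene", "PRS", "QRF", "FH")[c(x$use_gene, x$use_prs, x$use_qrf, x$use_fh)]
  cat("model_variant '", x$name, "': age",
      if (length(on)) paste0(" + ", paste(on, collapse = " + ")) else " only",
      "\n", sep = "")
  invisible(x)
}
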