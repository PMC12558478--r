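#' Synthetic reconstruction of the published per-facility call table
#'
#' A fully synthetic per-facility table of 492 health facilities (25
#' hospitals, 13 dialysis centers, 454 pharmacies) whose joint
#' distribution of model calls and gold labels is exactly consistent with
#' the published summary counts of the motivating 2023 Türkiye earthquake
#' assessment: per-type damaged margins (hospitals 5/25 model A and 3/25
#' model B; dialysis 0/13 and 1/13; pharmacies 46/454 and 17/454), the
#' pooled 2x2 model agreement table (13, 38, 8, 433) implied by the pooled
#' margins together with kappa = 0.32, the per-type kappas (0.41, 0,
#' 0.31), and the gold-standard accuracy counts for hospitals + dialysis
#' (sensitivity 3/7 for both models; specificity 29/31 model A, 30/31
#' model B). The individual facility identities are invented; only the
#' counts are faithful. Pharmacies carry no gold label.
#'
#' @return Tibble with `facility_id`, `ftype`, `city`, `call_a`, `call_b`
#'   (logical model calls) and `gold_label` (0/1 or NA).
#' @examples
#' tab <- demo_facility_calls()
#' table(tab$ftype, tab$call_a)
#' @export
demo_facility_calls <- function() {
  block <- function(ftype, n, call_a, call_b, gold) {
    tibble::tibble(ftype = ftype, call_a = rep(call_a, n),
                   call_b = rep(call_b, n), gold_label = rep(gold, n))
  }
  hospital <- dplyr::bind_rows(
    block("hospital", 2, TRUE, TRUE, 1L),    # both call the damage
    block("hospital", 1, TRUE, FALSE, 1L),   # A only
    block("hospital", 2, TRUE, FALSE, 0L),   # A false positives
    block("hospital", 1, FALSE, TRUE, 0L),   # B false positive
    block("hospital", 19, FALSE, FALSE, 0L))
  dialysis <- dplyr::bind_rows(
    block("dialysis", 1, FALSE, TRUE, 1L),   # B catches one
    block("dialysis", 3, FALSE, FALSE, 1L),  # both miss
    block("dialysis", 9, FALSE, FALSE, 0L))
  pharmacy <- dplyr::bind_rows(
    block("pharmacy", 11, TRUE, TRUE, NA_integer_),
    block("pharmacy", 35, TRUE, FALSE, NA_integer_),
    block("pharmacy", 6, FALSE, TRUE, NA_integer_),
    block("pharmacy", 402, FALSE, FALSE, NA_integer_))
  out <- dplyr::bind_rows(hospital, dialysis, pharmacy)
  out$facility_id <- sprintf("f%04d", seq_len(nrow(out)))
  out$city <- "combined"
  out[c("facility_id", "ftype", "city", "call_a", "call_b", "gold_label")]
}
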