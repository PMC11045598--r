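#' Pontius agreement decomposition of a reference/simulated crosstab
#'
#' Decomposes map agreement into quantity and location information
#' components. The crosstab rows are the reference map, the columns the
#' simulated map; with J classes, reference proportions q_j (row sums),
#' simulated proportions p_j (column sums), and observed proportion correct
#' P0 (the diagonal), the components are
#' \itemize{
#'   \item NQNL = 1/J (no quantity, no location information)
#'   \item MQNL = sum_j p_j q_j (medium quantity, no location)
#'   \item MQPL = sum_j min(p_j, q_j) (medium quantity, perfect location)
#'   \item NQPL = sum_j min(1/J, q_j)
#'   \item PQNL = sum_j q_j^2 (perfect quantity, no location)
#'   \item PQPL = 1
#' }
#' Location skill L = (P0 - MQNL)/(MQPL - MQNL) interpolates the
#' medium-location components: NQML = NQNL + L (NQPL - NQNL) and
#' PQML = PQNL + L (PQPL - PQNL). When MQPL = MQNL (degenerate marginals)
#' L is 1 if P0 = MQPL and flagged undefined (`NA`) otherwise.
#'
#' @param ct A [crosstab()] (reference as `map_t1`, simulated as `map_t2`)
#'   or a plain count/proportion matrix in that orientation.
#' @return An `agreement_components` list: `P0`, `J`, `p`, `q`, all
#'   component proportions, and `L`.
#' @export
agreement_components <- function(ct) {
  counts <- if (inherits(ct, "crosstab")) ct$counts else as.matrix(ct)
  total <- sum(counts)
  if (total <= 0) stop("empty crosstab")
  Pm <- counts / total
  J <- nrow(Pm)
  q <- rowSums(Pm)  # reference proportions
  p <- colSums(Pm)  # simulated proportions
  P0 <- sum(diag(Pm))
  NQNL <- 1 / J
  MQNL <- sum(p * q)
  MQPL <- sum(pmin(p, q))
  NQPL <- sum(pmin(NQNL, q))
  PQNL <- sum(q^2)
  PQPL <- 1
  tol <- 1e-12
  L <- if (MQPL - MQNL > tol) {
    (P0 - MQNL) / (MQPL - MQNL)
  } else if (abs(P0 - MQPL) <= tol) 1 else NA_real_
  NQML <- NQNL + L * (NQPL - NQNL)
  PQML <- PQNL + L * (PQPL - PQNL)
  structure(list(P0 = P0, J = J, p = p, q = q, NQNL = NQNL, MQNL = MQNL,
                 MQPL = MQPL, NQPL = NQPL, PQNL = PQNL, PQPL = PQPL,
                 NQML = NQML, PQML = PQML, L = L),
            class = "agreement_components")
}

#' @export
print.agreement_components <- function(x, ...) {
  cat(sprintf("<agreement_components> P0 = %.4f (J = %d)\n", x$P0, x$J))
  comp <- unlist(x[c("NQNL", "MQNL", "MQPL", "NQPL", "PQNL", "NQML",
                     "PQML", "L")])
  print(round(comp, 4))
  invisible(x)
}

#' Kno agreement statistic
#'
#' Kno = (P0 - NQNL)/(1 - NQNL): overall agreement against a no-information
#' baseline. Equals 1 iff P0 = 1; 0 at chance level.
#'
#' @param x An [agreement_components()] object or a [crosstab()].
#' @export
kno <- function(x) {
  if (!inherits(x, "agreement_components")) x <- agreement_components(x)
  if (x$J < 2) stop("Kno undefined for a single-class legend")
  (x$P0 - x$NQNL) / (1 - x$NQNL)
}

#' Klocation agreement statistic
#'
#' Klocation = (P0 - MQNL)/(MQPL - MQNL): ability to place classes at the
#' right locations given the maps' quantities. Equals the location skill L.
#'
#' @inheritParams kno
#' @export
klocation <- function(x) {
  if (!inherits(x, "agreement_components")) x <- agreement_components(x)
  x$L
}

#' Kquantity agreement statistic
#'
#' Kquantity = (P0 - NQML)/(PQML - NQML): ability to specify class
#' quantities given the observed location skill. Equals 1 when the
#' simulated marginals match the reference marginals (p = q), including the
#' degenerate case where numerator and denominator both vanish.
#'
#' @inheritParams kno
#' @export
kquantity <- function(x) {
  if (!inherits(x, "agreement_components")) x <- agreement_components(x)
  tol <- 1e-12
  den <- x$PQML - x$NQML
  if (is.na(den)) return(NA_real_)
  if (abs(den) <= tol) {
    if (abs(x$P0 - x$NQML) <= tol) return(1)
    return(NA_real_) # flagged undefined
  }
  (x$P0 - x$NQML) / den
}

#' Full agreement report between a simulated and a reference map
#'
#' @param reference,simulated [lulc_map()]s on the same grid.
#' @return List with the components and the three statistics.
#' @export
agreement_report <- function(reference, simulated) {
  comp <- agreement_components(crosstab(reference, simulated))
  list(components = comp, kno = kno(comp), klocation = klocation(comp),
       kquantity = kquantity(comp))
}
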