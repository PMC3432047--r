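# Synthetic stoichiometric networks with planted optima. Generation composes
# flux-carrying paths instead of sampling raw matrices: a bottlenecked uptake
# feeds a linear backbone into an objective sink, and extra one-to-one
# conversion reactions (planted flux zero) are wired between random internal
# metabolites. The planted vector therefore satisfies S v = 0 exactly, and
# because every internal reaction conserves molecule count and the uptake is
# the unique bottleneck, the FBA optimum equals the planted throughput.

#' Specification for a random synthetic model
#'
#' @param n_mets total metabolite count (>= 3; one external + internals).
#' @param n_rxns total reaction count (>= n_mets + 1: exchange, transporter,
#'   chain, sink).
#' @param rev_fraction fraction of the extra (off-backbone) reactions made
#'   reversible.
#' @param seed mandatory integer seed; fully determines the output.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_mets, n_rxns, rev_fraction = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_mets < 3) stop("impossible spec: need at least 3 metabolites")
  if (n_rxns < n_mets + 1)
    stop("impossible spec: need at least n_mets + 1 reactions ",
         "(exchange + transporter + chain + sink)")
  structure(list(n_mets = n_mets, n_rxns = n_rxns,
                 rev_fraction = rev_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random feasible model with a planted optimal solution
#'
#' @param spec a [synthetic_spec].
#' @return list(model, planted): `planted` is a `flux_distribution` holding
#'   the planted flux vector; its objective value equals the FBA optimum of
#'   the generated model.
#' @export
generate_random_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$n_mets - 1L            # internal metabolites
  internals <- sprintf("m%02d", seq_len(k))
  mets <- rbind(metabolite("s_e"),
                do.call(rbind, lapply(internals, metabolite)))
  u <- round(stats::runif(1, 0.5, 5), 3)
  rxns <- list(reaction("EX_s", c(s_e = -1), lower_bound = -u, upper_bound = Inf))
  rxns[["T_s"]] <- reaction("T_s", c(s_e = -1, m01 = 1))
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      id <- sprintf("C%02d", i)
      st <- stats::setNames(c(-1, 1), c(internals[i], internals[i + 1L]))
      rxns[[id]] <- reaction(id, st)
    }
  }
  rxns[["SINK"]] <- reaction("SINK", stats::setNames(-1, internals[k]),
                             is_exchange = TRUE)
  n_extra <- spec$n_rxns - length(rxns)
  for (e in seq_len(n_extra)) {
    ij <- sample(k, 2)   # distinct internal pair, 1:1 conversion
    id <- sprintf("X%02d", e)
    st <- stats::setNames(c(-1, 1), internals[ij])
    rev <- stats::runif(1) < spec$rev_fraction
    rxns[[id]] <- reaction(id, st, lower_bound = if (rev) -Inf else 0)
  }
  names(rxns)[1] <- "EX_s"
  model <- metabolic_model(mets, rxns, objective_id = "SINK")
  planted <- stats::setNames(numeric(length(rxns)), names(rxns))
  planted[c("EX_s")] <- -u
  planted[c("T_s", "SINK")] <- u
  if (k > 1) planted[sprintf("C%02d", seq_len(k - 1L))] <- u
  fd <- structure(list(flux = planted, objective_value = u, status = "optimal",
                       objective_id = "SINK", solver = list(backend = "planted")),
                  class = "flux_distribution")
  list(model = model, planted = fd)
}

#' Canonical hand-built toy models
#'
#' A named collection exercising every solver behaviour: `chain` (fully
#' determined), `parallel` (two stoichiometrically identical branches),
#' `atp_branch` (branches of differing ATP yield), `cycle3` (a
#' stoichiometrically balanced 3-cycle whose FVA widths hit the artificial
#' bound), and `maintenance` (a carbon/energy tradeoff where biomass falls
#' linearly with the maintenance drain: mu = (1 - m) / (1 + k) for drain m
#' and biomass ATP coefficient k, infeasible past m = 1).
#'
#' @return named list of `metabolic_model` objects.
#' @export
canonical_toys <- function() {
  toys <- list()
  mk <- function(ids, rxns, obj) {
    metabolic_model(do.call(rbind, lapply(ids, metabolite)), rxns,
                    objective_id = obj)
  }
  toys$chain <- mk(c("a_e", "a", "b"), list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1),
    reaction("T_a", c(a_e = -1, a = 1)),
    reaction("R1", c(a = -1, b = 1)),
    reaction("BM", c(b = -1), is_exchange = TRUE)), "BM")
  toys$parallel <- mk(c("a_e", "a", "b"), list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1),
    reaction("T_a", c(a_e = -1, a = 1)),
    reaction("B1", c(a = -1, b = 1)),
    reaction("B2", c(a = -1, b = 1)),
    reaction("BM", c(b = -1), is_exchange = TRUE)), "BM")
  toys$atp_branch <- mk(c("a_e", "a", "b", "atp", "adp"), list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1),
    reaction("T_a", c(a_e = -1, a = 1)),
    reaction("B_hi", c(a = -1, adp = -1, b = 1, atp = 1)),
    reaction("B_lo", c(a = -1, b = 1)),
    reaction("BM", c(b = -1, atp = -1, adp = 1), is_exchange = FALSE)), "BM")
  toys$cycle3 <- mk(c("a_e", "c1", "c2", "c3"), list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1),
    reaction("T_a", c(a_e = -1, c1 = 1)),
    reaction("L12", c(c1 = -1, c2 = 1), lower_bound = -Inf),
    reaction("L23", c(c2 = -1, c3 = 1), lower_bound = -Inf),
    reaction("L31", c(c3 = -1, c1 = 1), lower_bound = -Inf),
    reaction("BM", c(c1 = -1), is_exchange = TRUE)), "BM")
  toys$maintenance <- mk(c("a_e", "a", "b", "atp", "adp"), list(
    reaction("EX_a", c(a_e = -1), lower_bound = -1),
    reaction("T_a", c(a_e = -1, a = 1)),
    reaction("BURN", c(a = -1, adp = -1, atp = 1)),
    reaction("CONV", c(a = -1, b = 1)),
    reaction("R_ngam", c(atp = -1, adp = 1)),
    reaction("BM", c(b = -1, atp = -0.5, adp = 0.5), is_exchange = FALSE)), "BM")
  toys
}
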