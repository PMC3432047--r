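# Per-pathway energy accounting. A conversion (1 substrate -> stoichiometric
# product over a declared reaction set) is posed as a small steady-state LP
# in which only the allowed reactions plus cofactor-balancing slacks carry
# flux; the slack fluxes are the net ATP / NAD(P)H / NADH / FADH2 / reduced
# ferredoxin balances of the conversion. ATP equivalents use the respiratory
# P/O ratio (0.5 here): 1 ATP ~ 2 NAD(P)H, and ferredoxin-NADP+ reductase
# converts 2 reduced ferredoxin to 1 NAD(P)H.

#' ATP equivalents of a cofactor balance
#'
#' `atp + p_o * nadph + p_o * fd_red / 2`: at P/O = 0.5 two NAD(P)H equal
#' one ATP, and two reduced ferredoxin equal one NAD(P)H.
#'
#' @param atp,nadph,fd_red net mmol balances.
#' @param p_o P/O ratio (> 0).
#' @return ATP equivalents.
#' @export
atp_equivalents <- function(atp, nadph, fd_red = 0, p_o = 0.5) {
  stopifnot(p_o > 0)
  atp + p_o * nadph + p_o * fd_red / 2
}

#' Energy account of a pathway conversion
#'
#' Forces the conversion `substrate_amount` substrate -> `product_amount`
#' product at steady state using only `allowed` reactions, with free pools
#' for water, phosphate, CO2, bicarbonate, ammonia and coenzyme A, and
#' balancing slacks for the cofactor pairs ATP/ADP, NADP(H), NAD(H),
#' FAD(H2) and ferredoxin. Among feasible conversion modes the one with
#' maximal ATP equivalents is reported (a deterministic representative).
#'
#' @param model a `metabolic_model`.
#' @param substrate,product metabolite ids.
#' @param allowed character vector of reaction ids permitted to carry flux.
#' @param substrate_amount,product_amount forced amounts (default 1 each).
#' @param p_o P/O ratio for the ATP-equivalent summary.
#' @param free_mets metabolite ids given unconstrained pools.
#' @return object of class `"energy_account"`: net_atp, net_nadph, net_nadh,
#'   net_fadh2, net_fd_red, atp_equivalents (NADH and FADH2 are folded in at
#'   the same P/O weight as NAD(P)H).
#' @export
pathway_energy_account <- function(model, substrate, product, allowed,
                                   substrate_amount = 1, product_amount = 1,
                                   p_o = 0.5,
                                   free_mets = c("h2o", "pi", "co2", "hco3",
                                                 "nh3", "coa")) {
  missing_rxn <- setdiff(allowed, names(model$reactions))
  if (length(missing_rxn))
    stop("allowed reactions not in model: ", paste(missing_rxn, collapse = ", "))
  rxns <- model$reactions[allowed]
  slack <- list()
  pair <- function(id, from, to) {
    slack[[id]] <<- reaction(id, stats::setNames(c(-1, 1), c(from, to)),
                             lower_bound = -Inf, upper_bound = Inf,
                             is_exchange = FALSE)
  }
  slack[["BAL_atp"]] <- reaction("BAL_atp",
    c(atp = -1, h2o = -1, adp = 1, pi = 1), -Inf, Inf, is_exchange = FALSE)
  pair("BAL_nadph", "nadph", "nadp")
  pair("BAL_nadh", "nadh", "nad")
  pair("BAL_fadh2", "fadh2", "fad")
  pair("BAL_fd", "fdred", "fdox")
  for (fm in free_mets)
    slack[[paste0("FREE_", fm)]] <- reaction(paste0("FREE_", fm),
      stats::setNames(-1, fm), -Inf, Inf, is_exchange = TRUE)
  slack[["SUB_in"]] <- reaction("SUB_in", stats::setNames(1, substrate),
                                substrate_amount, substrate_amount,
                                is_exchange = TRUE)
  slack[["PROD_out"]] <- reaction("PROD_out", stats::setNames(-1, product),
                                  product_amount, product_amount,
                                  is_exchange = TRUE)
  all_rxns <- c(rxns, slack)
  mids <- unique(unlist(lapply(all_rxns, function(r) names(r$stoichiometry))))
  mets <- model$metabolites[model$metabolites$id %in% mids, , drop = FALSE]
  extra <- setdiff(mids, mets$id)
  if (length(extra))
    mets <- rbind(mets, do.call(rbind, lapply(extra, metabolite)))
  sub <- metabolic_model(mets, all_rxns)
  dat <- lp_data_for(sub)
  obj <- numeric(length(dat$rxn_ids))
  w <- c(BAL_atp = 1, BAL_nadph = p_o, BAL_nadh = p_o, BAL_fadh2 = p_o,
         BAL_fd = p_o / 2)
  for (nm in names(w)) obj[match(nm, dat$rxn_ids)] <- w[[nm]]
  res <- solve_lp(obj, dat$S, numeric(nrow(dat$S)), dat$lb, dat$ub,
                  maximize = TRUE)
  if (res$status != "optimal")
    stop("no feasible conversion mode from '", substrate, "' to '", product,
         "' within the allowed reaction set (", res$status, ")")
  v <- stats::setNames(res$x, dat$rxn_ids)
  acct <- list(net_atp = unname(v["BAL_atp"]),
               net_nadph = unname(v["BAL_nadph"]),
               net_nadh = unname(v["BAL_nadh"]),
               net_fadh2 = unname(v["BAL_fadh2"]),
               net_fd_red = unname(v["BAL_fd"]),
               p_o = p_o,
               flux = v[allowed])
  acct$atp_equivalents <- atp_equivalents(acct$net_atp,
                                          acct$net_nadph + acct$net_nadh +
                                            acct$net_fadh2,
                                          acct$net_fd_red, p_o)
  class(acct) <- "energy_account"
  acct
}

#' @export
print.energy_account <- function(x, ...) {
  cat(sprintf(paste0("energy account: ATP %+.3f, NAD(P)H %+.3f, NADH %+.3f, ",
                     "FADH2 %+.3f, Fd_red %+.3f; ATP-eq %+.3f at P/O %.2f\n"),
              x$net_atp, x$net_nadph, x$net_nadh, x$net_fadh2, x$net_fd_red,
              x$atp_equivalents, x$p_o))
  invisible(x)
}
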