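# Toy branch-point models with analytically known ground truth.
#
# Structure (mirroring the chorismate node): substrate exchange ->
# transport -> a supply reaction into a hub metabolite; the hub feeds
# biomass-coupled amino-acid branches (each consumed by biomass 1:1), free
# sink branches (demand-drained overflow, the structural "place to hide"
# flux that adversarial minimization exploits), and a graftable product
# branch with its own exchange. All closed-form truths below follow from
# the single hub balance.

#' Specification of a generated toy model
#'
#' @param n_bio_branches biomass-coupled hub branches (>= 1; biomass
#'   consumes one unit from each).
#' @param n_free_branches free overflow branches with demand sinks (>= 0).
#' @param uptake substrate uptake bound (mmol/gDW/h).
#' @param wt_uptake the wild-type measured substrate uptake written to the
#'   fixture flux table (must be < `uptake` so supply is classifiable as
#'   MUST-U; default 0.8 * uptake).
#' @param product_yield product per hub metabolite through the product
#'   branch (rational).
#' @param branch_yields amino acid per hub metabolite for each bio branch
#'   (length `n_bio_branches`, recycled).
#' @param seed random seed controlling the GPR templates.
#' @return a `toy_spec` list with a `ground_truth` record; the ground
#'   truth is computed in closed form from the parameters, never from an
#'   LP.
#' @export
toy_spec <- function(n_bio_branches = 2L, n_free_branches = 1L, uptake = 10,
                     wt_uptake = 0.8 * uptake, product_yield = 1,
                     branch_yields = 1, seed = 1L) {
  if (n_bio_branches < 1L) stop("biomass unsatisfiable: need at least one biomass-coupled branch")
  if (n_bio_branches + n_free_branches > 3L) {
    stop("at most 3 hub branches in total (keeps generated toys within the rational oracle's 12-reaction guard)")
  }
  if (uptake <= 0) stop("uptake must be positive")
  if (wt_uptake <= 0 || wt_uptake >= uptake) {
    stop("wt_uptake must lie strictly between 0 and the uptake bound")
  }
  branch_yields <- rep(branch_yields, length.out = n_bio_branches)
  spec <- list(n_bio_branches = as.integer(n_bio_branches),
               n_free_branches = as.integer(n_free_branches),
               uptake = uptake, wt_uptake = wt_uptake,
               product_yield = product_yield, branch_yields = branch_yields,
               seed = as.integer(seed))
  spec$ground_truth <- toy_ground_truth(spec)
  structure(spec, class = "toy_spec")
}

# closed-form ground truth (see vignette): with inverse-yield sum
# q = sum(1/y_i), max growth = U/q; theoretical max product = yp*U;
# envelope upper boundary yp*(U - q*b); under thresholds (g, p) with
# g + p = 1 the overproducer state is fully pinned, giving the unique
# minimal FORCE set {up supply @ U, down each bio branch @ g*U/(q*y_i),
# ko each free branch} with worst-case minimum p*yp*U.
toy_ground_truth <- function(spec, g = 0.2, p = 0.8) {
  q <- sum(1 / spec$branch_yields)
  U <- spec$uptake
  yp <- spec$product_yield
  max_growth <- U / q
  theo <- yp * U
  down_levels <- g * U / (q * spec$branch_yields)
  force <- data.frame(
    reaction_id = c("R_supply",
                    paste0("R_bio", seq_len(spec$n_bio_branches)),
                    if (spec$n_free_branches > 0)
                      paste0("R_free", seq_len(spec$n_free_branches))),
    kind = c("up", rep("down", spec$n_bio_branches),
             rep("ko", spec$n_free_branches)),
    level = c(U, down_levels, rep(NA_real_, spec$n_free_branches)),
    stringsAsFactors = FALSE)
  force <- force[order(force$reaction_id), , drop = FALSE]
  rownames(force) <- NULL
  list(max_growth = max_growth,
       theoretical_max_product = theo,
       envelope_product_at_zero_growth = theo,
       envelope_product_at_max_growth = 0,
       force_set = force,
       worst_case_min_product = p * theo,
       growth_fraction = g, product_fraction = p)
}

# GPR templates drawn per branch; gene cost of forcing each kind is known
# structurally (up single = 1; down "a and b" = 1; down "a or b" = 2).
toy_gpr_templates <- function(stub, rng_draw) {
  switch(rng_draw,
         `1` = list(gpr = paste0(stub, "A"), down_cost = 1L),
         `2` = list(gpr = paste0(stub, "A and ", stub, "B"), down_cost = 1L),
         `3` = list(gpr = paste0(stub, "A or ", stub, "B"), down_cost = 2L))
}

#' Generate a toy model from a specification
#'
#' Deterministic for a given spec (same seed, same model). The returned
#' model is already grafted with its product branch; close it with
#' [close_pathway()] for the wild-type reference. The spec's ground truth
#' and a fixture flux-data table (fixing substrate uptake at the measured
#' wild-type value) are attached as attributes `toy_spec` and
#' `flux_data`.
#'
#' @param spec a [toy_spec()].
#' @return a `cbm_model`.
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  rng <- local({
    set.seed(spec$seed)
    sample.int(3L, spec$n_bio_branches + spec$n_free_branches + 1L,
               replace = TRUE)
  })
  kb <- spec$n_bio_branches; kf <- spec$n_free_branches
  mets <- rbind(
    metabolite("sub_e", "substrate", "e"),
    metabolite("sub_c", "substrate", "c"),
    metabolite("hub_c", "hub metabolite", "c"))
  for (i in seq_len(kb)) mets <- rbind(mets, metabolite(paste0("aa", i, "_c"),
                                                        paste0("amino acid ", i), "c"))
  for (i in seq_len(kf)) mets <- rbind(mets, metabolite(paste0("sink", i, "_c"),
                                                        paste0("overflow sink ", i), "c"))
  mets <- rbind(mets, metabolite("prod_e", "product", "e"))

  supply_gpr <- toy_gpr_templates("sup", as.character(1L))   # single gene, cost 1
  rxns <- list(
    reaction("EX_sub", c(sub_e = -1), -spec$uptake, 1000, name = "substrate exchange"),
    reaction("T_sub", c(sub_e = -1, sub_c = 1), 0, 1000, name = "substrate transport"),
    reaction("R_supply", c(sub_c = -1, hub_c = 1), 0, 1000,
             gpr = supply_gpr$gpr, name = "hub supply"))
  bio_cost <- integer(kb)
  biomass_st <- numeric(0)
  for (i in seq_len(kb)) {
    tp <- toy_gpr_templates(paste0("bio", i), as.character(rng[i + 1L]))
    bio_cost[i] <- tp$down_cost
    st <- stats::setNames(c(-1, spec$branch_yields[i]),
                          c("hub_c", paste0("aa", i, "_c")))
    # each amino acid both feeds biomass and has a free demand sink; the
    # sink decouples the branch fluxes so that capping one branch does not
    # implicitly cap the others through the biomass coupling
    rxns <- c(rxns, list(
      reaction(paste0("R_bio", i), st, 0, 1000, gpr = tp$gpr,
               name = paste0("biomass branch ", i)),
      reaction(paste0("DM_aa", i), stats::setNames(-1, paste0("aa", i, "_c")),
               0, 1000, name = paste0("amino acid demand ", i))))
    biomass_st[paste0("aa", i, "_c")] <- -1
  }
  free_cost <- integer(kf)
  for (i in seq_len(kf)) {
    tp <- toy_gpr_templates(paste0("ovf", i), as.character(rng[kb + i + 1L]))
    free_cost[i] <- if (rng[kb + i + 1L] == 2L) 1L else if (rng[kb + i + 1L] == 3L) 2L else 1L
    st <- stats::setNames(c(-1, 1), c("hub_c", paste0("sink", i, "_c")))
    rxns <- c(rxns, list(
      reaction(paste0("R_free", i), st, 0, 1000, gpr = tp$gpr,
               name = paste0("overflow branch ", i)),
      reaction(paste0("DM_sink", i),
               stats::setNames(-1, paste0("sink", i, "_c")), 0, 1000,
               name = paste0("overflow demand ", i))))
  }
  rxns <- c(rxns, list(
    reaction("BIOMASS", biomass_st, 0, 1000, name = "biomass"),
    reaction("R_product", c(hub_c = -1, prod_e = spec$product_yield), 0, 1000,
             gpr = "papX", name = "product branch"),
    reaction("EX_prod", c(prod_e = -1), 0, 1000, name = "product exchange")))

  mod <- cbm_model(paste0("toy_branchpoint_seed", spec$seed), mets, rxns,
                   "BIOMASS")
  attr(mod, "product_exchange_id") <- "EX_prod"
  attr(mod, "pathway_reaction_ids") <- c("R_product", "EX_prod")
  # gene-level cost of the minimal FORCE set (structural, from templates)
  spec$ground_truth$gene_cost <- 1L + sum(bio_cost) + sum(free_cost)
  attr(mod, "toy_spec") <- spec
  attr(mod, "flux_data") <- data.frame(
    reaction_id = "EX_sub", lower = -spec$wt_uptake, upper = -spec$wt_uptake,
    stringsAsFactors = FALSE)
  mod
}

#' The canonical toy fixture ("toy_chor_v1")
#'
#' A deterministic structural mimic of the chorismate node (10 host
#' reactions plus the 2-reaction product branch): glucose-like substrate ->
#' transport -> hub supply (GPR `aroT`); hub branches to a tryptophan-like
#' sink (`trpA1 and trpA2`), a phenylalanine-like sink (`pheA or tyrA`),
#' an enterochelin-like overflow branch (`entA`, demand-drained), and a
#' product branch (`papA`) with its exchange; biomass consumes one
#' trp-like plus one phe-like unit, and each amino acid also has a free
#' demand sink (the overflow that adversarial minimization exploits).
#'
#' Exact ground truth (closed form, confirmed by the rational oracle):
#' maximum biomass 5, theoretical maximum product 10 (yield 1 mol/mol),
#' envelope upper boundary `10 - 2 b`, unique minimal FORCE set
#' \{up R_chor >= 10, down R_trp <= 1, down R_phe <= 1, ko R_ent\} with
#' worst-case minimum product 8 (80\% of theoretical maximum), gene-level
#' cost 5 (aroT; one of trpA1/trpA2; pheA and tyrA; entA).
#'
#' @param include_product_branch graft the product branch (default TRUE);
#'   `FALSE` returns the 8-reaction host for grafting tests.
#' @return a `cbm_model` with attributes `toy_spec` (ground truth) and
#'   `flux_data` (wild-type glucose uptake fixed at 8).
#' @export
toy_chor_model <- function(include_product_branch = TRUE) {
  mets <- rbind(
    metabolite("glc_e", "glucose", "e"),
    metabolite("glc_c", "glucose", "c"),
    metabolite("chor_c", "chorismate-like hub", "c"),
    metabolite("trp_c", "tryptophan-like", "c"),
    metabolite("phe_c", "phenylalanine-like", "c"),
    metabolite("ent_c", "enterochelin-like", "c"),
    metabolite("paf_e", "product", "e"))
  rxns <- list(
    reaction("EX_glc", c(glc_e = -1), -10, 1000, name = "glucose exchange"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), 0, 1000, name = "glucose transport"),
    reaction("R_chor", c(glc_c = -1, chor_c = 1), 0, 1000, gpr = "aroT",
             name = "hub supply"),
    reaction("R_trp", c(chor_c = -1, trp_c = 1), 0, 1000,
             gpr = "trpA1 and trpA2", name = "trp branch"),
    reaction("DM_trp", c(trp_c = -1), 0, 1000, name = "trp demand"),
    reaction("R_phe", c(chor_c = -1, phe_c = 1), 0, 1000,
             gpr = "pheA or tyrA", name = "phe branch"),
    reaction("DM_phe", c(phe_c = -1), 0, 1000, name = "phe demand"),
    reaction("R_ent", c(chor_c = -1, ent_c = 1), 0, 1000, gpr = "entA",
             name = "ent overflow branch"),
    reaction("DM_ent", c(ent_c = -1), 0, 1000, name = "ent demand"),
    reaction("BIOMASS", c(trp_c = -1, phe_c = -1), 0, 1000, name = "biomass"))
  if (include_product_branch) {
    mets_all <- mets
    rxns <- c(rxns, list(
      reaction("R_pap", c(chor_c = -1, paf_e = 1), 0, 1000, gpr = "papA",
               name = "product branch"),
      reaction("EX_paf", c(paf_e = -1), 0, 1000, name = "product exchange")))
  } else {
    mets_all <- mets[mets$id != "paf_e", , drop = FALSE]
  }
  mod <- cbm_model("toy_chor_v1", mets_all, rxns, "BIOMASS")
  if (include_product_branch) {
    attr(mod, "product_exchange_id") <- "EX_paf"
    attr(mod, "pathway_reaction_ids") <- c("R_pap", "EX_paf")
  }
  gt <- list(max_growth = 5, theoretical_max_product = 10,
             envelope_product_at_zero_growth = 10,
             envelope_product_at_max_growth = 0,
             force_set = data.frame(
               reaction_id = c("R_chor", "R_ent", "R_phe", "R_trp"),
               kind = c("up", "ko", "down", "down"),
               level = c(10, NA, 1, 1), stringsAsFactors = FALSE),
             worst_case_min_product = 8,
             growth_fraction = 0.2, product_fraction = 0.8,
             gene_cost = 5L)
  attr(mod, "toy_spec") <- list(ground_truth = gt)
  attr(mod, "flux_data") <- data.frame(
    reaction_id = "EX_glc", lower = -8, upper = -8, stringsAsFactors = FALSE)
  mod
}

#' Toy product pathway for grafting tests
#'
#' The product branch of the canonical toy as a standalone
#' `pathway_definition`, graftable onto `toy_chor_model(FALSE)`.
#' @return a `pathway_definition`.
#' @export
toy_product_pathway <- function() {
  pathway_definition(
    metabolites = metabolite("paf_e", "product", "e"),
    reactions = list(
      reaction("R_pap", c(chor_c = -1, paf_e = 1), 0, 1000, gpr = "papA",
               name = "product branch"),
      reaction("EX_paf", c(paf_e = -1), 0, 1000, name = "product exchange")),
    product_exchange_id = "EX_paf",
    notes = c(R_pap = "toy product branch", EX_paf = "toy product exchange"))
}

#' Run the full strain-design pipeline on a toy model
#'
#' Convenience wrapper used by the recovery experiments: wild-type ranges
#' (pathway closed, fixture flux data, 0.9 growth floor), overproducer
#' ranges, MUST classification, candidate construction (pathway excluded),
#' and FORCE search sized to the ground-truth set.
#'
#' @param model a toy model from [generate_toy_model()] / [toy_chor_model()].
#' @param thresholds a [design_thresholds()].
#' @param solver backend name or `NULL`.
#' @param wt_growth_fraction growth floor fraction for the wild-type FVA.
#' @return list (`wt_ranges`, `ov_ranges`, `must`, `candidates`, `force`).
#' @export
toy_pipeline <- function(model, thresholds = design_thresholds(),
                         solver = NULL, wt_growth_fraction = 0.9) {
  wt <- close_pathway(model)
  fd <- attr(model, "flux_data")
  class(fd) <- c("flux_data", "data.frame")
  wt_ranges <- wildtype_ranges(wt, fd, growth_fraction = wt_growth_fraction,
                               solver = solver)
  ov_ranges <- overproducer_ranges(model, thresholds, solver = solver)
  must <- classify_must_sets(wt_ranges, ov_ranges, thresholds$epsilon)
  cand <- candidate_interventions(must, model,
                                  exclude_reactions = pathway_reactions(model))
  force <- find_force_sets(model, cand, k_max = nrow(cand),
                           thresholds = thresholds, solver = solver)
  list(wt_ranges = wt_ranges, ov_ranges = ov_ranges, must = must,
       candidates = cand, force = force)
}
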