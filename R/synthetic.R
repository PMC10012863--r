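# Synthetic multi-clinic cohort generator. The base ground-truth network is
# hand-authored with clinically plausible dependencies (palliative intent ->
# short hypofractionated courses; breast 3D plans -> two tangent-like beams
# with wedges; VMAT -> high MU/cGy but low MU/degree; total dose ~ dose per
# fraction x number of fractions), so the synthetic data carry the dependency
# structure the reviewer network is meant to exploit, without claiming
# fidelity to any real institution.

row_norm <- function(w, floor = 1e-4) {
  w <- w + floor
  w / sum(w)
}

# wrapped-Gaussian mixture over the 36 angle bins (centers 5, 15, ..., 355)
angle_mix <- function(centers, sds, weights, uniform = 0.02) {
  mids <- seq(5, 355, by = 10)
  w <- rep(uniform / 36, 36)
  for (i in seq_along(centers)) {
    d <- abs(mids - centers[i])
    d <- pmin(d, 360 - d)
    w <- w + weights[i] * exp(-0.5 * (d / sds[i])^2)
  }
  w
}

# shift probability mass of an ordered-bin distribution up (k>0) or down (k<0)
shift_mass <- function(p, k) {
  n <- length(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- min(max(i + k, 1L), n)
    out[j] <- out[j] + p[i]
  }
  out
}

#' Hand-authored base ground-truth network
#'
#' The generating model for synthetic cohorts: the default 24-node structure
#' with conditional probability tables authored to reflect broad clinical
#' practice patterns (fractionation by intent and site, beam geometry by
#' technique and laterality, complexity surrogates by technique). Every entry
#' is strictly positive.
#'
#' @param schema schema tibble.
#' @param structure edge tibble.
#' @return An [rt_network()].
#' @export
base_network <- function(schema = default_schema(),
                         structure = default_structure()) {
  states <- setNames(schema$states, schema$variable)
  parents <- structure_parents(structure, schema$variable)

  make_cpt <- function(node, fun) {
    ps <- parents[[node]]
    st <- states[[node]]
    if (length(ps) == 0) {
      prob <- matrix(row_norm(fun(list())), nrow = 1)
    } else {
      grid <- expand.grid(lapply(ps, function(p) states[[p]]),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      names(grid) <- ps
      prob <- t(apply(grid, 1, function(row) row_norm(fun(as.list(row)))))
    }
    colnames(prob) <- st
    list(parents = ps, prob = prob)
  }

  locs <- states$tumor_location
  loc_w <- c(breast = .28, lung = .22, prostate = .18, head_neck = .12,
             rectum = .12, brain = .08)

  cpts <- list()
  cpts$tumor_location <- make_cpt("tumor_location", function(pa) loc_w)

  t_by_loc <- rbind(breast = c(.45, .35, .15, .05), lung = c(.2, .3, .3, .2),
                    prostate = c(.3, .4, .2, .1), head_neck = c(.2, .3, .25, .25),
                    rectum = c(.15, .35, .35, .15), brain = c(.4, .3, .2, .1))
  cpts$t_stage <- make_cpt("t_stage", function(pa) t_by_loc[pa$tumor_location, ])

  n_by_loc <- rbind(breast = c(.6, .3, .1), lung = c(.4, .3, .3),
                    prostate = c(.8, .15, .05), head_neck = c(.35, .35, .3),
                    rectum = c(.45, .35, .2), brain = c(.9, .07, .03))
  cpts$n_stage <- make_cpt("n_stage", function(pa) n_by_loc[pa$tumor_location, ])

  m1 <- c(breast = .1, lung = .25, prostate = .12, head_neck = .08,
          rectum = .18, brain = .02)
  cpts$m_stage <- make_cpt("m_stage", function(pa) {
    p <- m1[[pa$tumor_location]]; c(1 - p, p)
  })

  pal_base <- c(breast = .08, lung = .3, prostate = .1, head_neck = .1,
                rectum = .15, brain = .25)
  cpts$treatment_intent <- make_cpt("treatment_intent", function(pa) {
    p <- pal_base[[pa$tumor_location]]
    if (pa$m_stage == "M1") p <- min(.95, p + .6)
    if (pa$t_stage == "T4") p <- min(.95, p + .15)
    c(curative = 1 - p, palliative = p)
  })

  lat_by_loc <- rbind(breast = c(.48, .48, .04), lung = c(.45, .45, .1),
                      prostate = c(.02, .02, .96), head_neck = c(.15, .15, .7),
                      rectum = c(.02, .02, .96), brain = c(.35, .35, .3))
  cpts$laterality <- make_cpt("laterality", function(pa) lat_by_loc[pa$tumor_location, ])

  tech_cur <- rbind(breast = c(.35, .25, .3, .1), lung = c(.5, .25, .2, .05),
                    prostate = c(.7, .25, .04, .01), head_neck = c(.6, .35, .04, .01),
                    rectum = c(.45, .3, .24, .01), brain = c(.5, .3, .15, .05))
  cpts$treatment_technique <- make_cpt("treatment_technique", function(pa) {
    base <- tech_cur[pa$tumor_location, ]
    if (pa$treatment_intent == "palliative") {
      base <- 0.3 * base + 0.7 * c(.12, .08, .75, .05)
    }
    base
  })

  ig_by_tech <- rbind(VMAT = c(.75, .2, .05), IMRT = c(.7, .25, .05),
                      `3DCRT` = c(.3, .5, .2), electrons = c(.05, .25, .7))
  cpts$image_guidance <- make_cpt("image_guidance", function(pa) {
    base <- ig_by_tech[pa$treatment_technique, ]
    if (pa$treatment_intent == "palliative") base <- 0.5 * base + 0.5 * c(.15, .5, .35)
    base
  })

  nfx_cur <- rbind(
    breast    = c(.02, .03, .10, .35, .30, .12, .06, .02, .00),
    lung      = c(.06, .05, .08, .15, .18, .25, .15, .06, .02),
    prostate  = c(.12, .03, .05, .30, .10, .10, .10, .18, .02),
    head_neck = c(.01, .02, .03, .08, .12, .20, .40, .12, .02),
    rectum    = c(.30, .05, .05, .10, .35, .10, .03, .01, .01),
    brain     = c(.25, .05, .15, .10, .10, .25, .08, .01, .01))
  nfx_pal <- c(.60, .30, .06, .02, .01, .005, .003, .001, .001)
  cpts$number_of_fractions <- make_cpt("number_of_fractions", function(pa) {
    if (pa$treatment_intent == "palliative") nfx_pal else nfx_cur[pa$tumor_location, ]
  })

  # dose-per-fraction bins: [0,50) ... [450,500), >=500
  dpf_cur <- rbind(
    breast    = c(.00, .01, .01, .05, .35, .45, .08, .02, .01, .01, .01),
    lung      = c(.00, .01, .02, .12, .45, .12, .05, .03, .02, .02, .16),
    prostate  = c(.00, .01, .01, .08, .30, .25, .15, .03, .02, .01, .14),
    head_neck = c(.00, .01, .02, .15, .65, .10, .03, .01, .01, .01, .01),
    rectum    = c(.00, .01, .02, .35, .30, .05, .02, .01, .01, .01, .22),
    brain     = c(.00, .01, .02, .30, .30, .10, .08, .02, .01, .01, .15))
  dpf_pal <- c(.00, .01, .01, .03, .10, .06, .45, .06, .13, .02, .13)
  cpts$dose_per_fraction <- make_cpt("dose_per_fraction", function(pa) {
    if (pa$treatment_intent == "palliative") dpf_pal else dpf_cur[pa$tumor_location, ]
  })

  # total dose concentrates on the product of the bin representatives
  dpf_rule <- binning_rule(default_binning(schema), "dose_per_fraction")
  nfx_rule <- binning_rule(default_binning(schema), "number_of_fractions")
  ptv_rule <- binning_rule(default_binning(schema), "ptv_dose")
  ptv_states <- states$ptv_dose
  cpts$ptv_dose <- make_cpt("ptv_dose", function(pa) {
    total <- state_midpoint(nfx_rule, pa$number_of_fractions) *
      state_midpoint(dpf_rule, pa$dose_per_fraction)
    hit <- match(bin_value(total, ptv_rule), ptv_states)
    w <- rep(.002, length(ptv_states))
    w[hit] <- w[hit] + .78
    if (hit > 1) w[hit - 1] <- w[hit - 1] + .1
    if (hit < length(w)) w[hit + 1] <- w[hit + 1] + .1
    w
  })

  cpts$radiation_type <- make_cpt("radiation_type", function(pa) {
    if (pa$treatment_technique == "electrons") c(.03, .97) else c(.995, .005)
  })

  # beam energies: 6MV 10MV 15MV 6FFF 10FFF 6MeV 9MeV 12MeV
  en_photon <- rbind(VMAT = c(.52, .18, .02, .17, .09, 0, 0, 0),
                     IMRT = c(.68, .2, .08, .02, .01, 0, 0, 0),
                     `3DCRT` = c(.5, .25, .22, .01, .01, 0, 0, 0),
                     electrons = c(.6, .25, .13, .01, .01, 0, 0, 0))
  en_elec <- c(0, 0, 0, 0, 0, .35, .42, .23)
  cpts$beam_energy <- make_cpt("beam_energy", function(pa) {
    if (pa$radiation_type == "electron") en_elec else en_photon[pa$treatment_technique, ]
  })

  nb_by_tech <- rbind(VMAT = c(.25, .55, .13, .04, .02, .005, .005),
                      IMRT = c(.01, .02, .07, .1, .35, .33, .12),
                      `3DCRT` = c(.06, .34, .26, .22, .1, .015, .005),
                      electrons = c(.85, .12, .02, .005, .003, .001, .001))
  cpts$number_of_beams <- make_cpt("number_of_beams", function(pa) {
    base <- nb_by_tech[pa$treatment_technique, ]
    if (pa$tumor_location == "breast" && pa$treatment_technique == "3DCRT") {
      base <- c(.05, .7, .12, .08, .04, .005, .005)
    }
    base
  })

  cpts$gantry_angle <- make_cpt("gantry_angle", function(pa) {
    if (pa$treatment_technique == "VMAT") {
      angle_mix(c(179, 181), c(40, 40), c(.5, .5), uniform = 1.2)
    } else if (pa$treatment_technique == "electrons") {
      angle_mix(c(0), c(20), c(1), uniform = .1)
    } else {
      switch(pa$laterality,
             left = angle_mix(c(125, 305), c(22, 22), c(.5, .5)),
             right = angle_mix(c(55, 235), c(22, 22), c(.5, .5)),
             midline = angle_mix(c(0, 180), c(28, 28), c(.55, .45)))
    }
  })

  cpts$collimator_angle <- make_cpt("collimator_angle", function(pa) {
    base <- switch(pa$treatment_technique,
                   `3DCRT` = angle_mix(c(0), c(12), c(1), uniform = .15),
                   electrons = angle_mix(c(0), c(10), c(1), uniform = .1),
                   angle_mix(c(0, 15, 345), c(10, 12, 12), c(.45, .25, .25),
                             uniform = .2))
    if (pa$tumor_location == "breast") {
      base <- base + angle_mix(c(10, 350), c(10, 10), c(.3, .3), uniform = 0)
    }
    base
  })

  ssd_photon <- c(.01, .08, .28, .45, .14, .04)
  ssd_elec <- c(.01, .02, .05, .2, .64, .08)
  cpts$ssd <- make_cpt("ssd", function(pa) {
    if (pa$radiation_type == "electron") ssd_elec else ssd_photon
  })

  bolus_yes <- c(breast = .3, lung = .03, prostate = .01, head_neck = .22,
                 rectum = .05, brain = .01)
  cpts$bolus <- make_cpt("bolus", function(pa) {
    p <- if (pa$radiation_type == "electron") .5 else bolus_yes[[pa$tumor_location]]
    c(p, 1 - p)
  })

  orient_by_loc <- rbind(breast = c(.96, .01, .03), lung = c(.95, .02, .03),
                         prostate = c(.9, .04, .06), head_neck = c(.98, .01, .01),
                         rectum = c(.8, .17, .03), brain = c(.97, .02, .01))
  cpts$patient_orientation <- make_cpt("patient_orientation", function(pa)
    orient_by_loc[pa$tumor_location, ])

  cpts$table_angle <- make_cpt("table_angle", function(pa) {
    base <- switch(pa$treatment_technique,
                   VMAT = angle_mix(c(0), c(6), c(1), uniform = .04),
                   IMRT = angle_mix(c(0, 30, 330), c(6, 15, 15), c(.8, .08, .08),
                                    uniform = .04),
                   `3DCRT` = angle_mix(c(0), c(6), c(1), uniform = .05),
                   electrons = angle_mix(c(0), c(8), c(1), uniform = .1))
    if (pa$patient_orientation != "HFS") base <- base + angle_mix(c(0), c(15), c(.2), uniform = .05)
    base
  })

  cpts$tolerance_table <- make_cpt("tolerance_table", function(pa) {
    if (pa$radiation_type == "electron") c(.05, .01, .9, .04)
    else if (pa$treatment_technique == "VMAT") c(.78, .15, .01, .06)
    else c(.85, .03, .02, .1)
  })

  mu_cgy_by_tech <- rbind(VMAT = c(.03, .22, .45, .25, .05),
                          IMRT = c(.01, .07, .42, .38, .12),
                          `3DCRT` = c(.2, .65, .12, .02, .01),
                          electrons = c(.45, .45, .07, .02, .01))
  cpts$mu_per_cgy <- make_cpt("mu_per_cgy", function(pa) {
    base <- mu_cgy_by_tech[pa$treatment_technique, ]
    nb <- match(pa$number_of_beams, states$number_of_beams)
    shift_mass(base, as.integer(nb >= 6) - as.integer(nb <= 1))
  })

  mu_deg_vmat <- c(.18, .42, .3, .08, .02)
  mu_deg_fixed <- c(.01, .03, .12, .32, .52)
  cpts$mu_per_degree <- make_cpt("mu_per_degree", function(pa) {
    base <- if (pa$treatment_technique == "VMAT") mu_deg_vmat else mu_deg_fixed
    mu <- match(pa$mu_per_cgy, states$mu_per_cgy)
    shift_mass(base, as.integer(mu >= 4) - as.integer(mu <= 1))
  })

  cpts$wedge <- make_cpt("wedge", function(pa) {
    if (pa$treatment_technique %in% c("VMAT", "IMRT")) c(.97, .01, .02)
    else if (pa$tumor_location == "breast") c(.35, .35, .3)
    else c(.6, .22, .18)
  })

  rt_network(structure, cpts, schema)
}

#' Build divergent clinic profiles from a base network
#'
#' Each clinic's ground truth shares the base structure; its CPT rows are
#' drawn from a Dirichlet distribution centred on the base row with
#' concentration `20 / divergence` (so `divergence = 0` leaves all clinics
#' identical to the base, and larger values push clinics further apart). This
#' single scalar reproduces the similar-versus-divergent clinic axis of
#' multi-site validation. Seeded and reproducible.
#'
#' @param base base [rt_network()].
#' @param clinic_ids clinic identifiers.
#' @param divergence non-negative scalar; see above.
#' @param seed integer seed.
#' @param inapplicable named list: clinic id -> variables structurally not
#'   recorded there (sampled, then dropped).
#' @param missingness named numeric vector of per-variable
#'   missing-at-random rates, applied to every clinic.
#' @param size_hint default cohort size stored on each profile.
#' @return A list of `rt_clinic_profile` objects.
#' @export
build_profiles <- function(base, clinic_ids = c("clinic_A", "clinic_B", "clinic_C"),
                           divergence = 1.5, seed = 1L,
                           inapplicable = NULL, missingness = NULL,
                           size_hint = 2000L) {
  if (divergence < 0) abort("divergence must be >= 0",
                            class = "planreviewr_generator_error")
  inapplicable <- inapplicable %||% default_inapplicable(clinic_ids)
  missingness <- missingness %||% default_missingness()
  lapply(seq_along(clinic_ids), function(i) {
    cl <- clinic_ids[i]
    net <- if (divergence == 0) base else {
      perturb_network(base, conc = 20 / divergence,
                      seed = derive_seed(seed, 100 + i))
    }
    structure(list(clinic_id = cl, ground_truth = net,
                   inapplicable = inapplicable[[cl]] %||% character(0),
                   missingness = missingness, size_hint = size_hint),
              class = "rt_clinic_profile")
  })
}

default_inapplicable <- function(clinic_ids) {
  out <- setNames(vector("list", length(clinic_ids)), clinic_ids)
  if ("clinic_A" %in% clinic_ids) out$clinic_A <- c("wedge", "tolerance_table")
  if ("clinic_B" %in% clinic_ids) out$clinic_B <- "bolus"
  out
}

default_missingness <- function() {
  c(t_stage = .05, n_stage = .05, m_stage = .05, ssd = .05,
    image_guidance = .03, wedge = .02)
}

perturb_network <- function(base, conc, seed) {
  cpts <- base$cpts
  with_seed(seed, {
    for (v in base$nodes) {
      p <- cpts[[v]]$prob
      for (j in seq_len(nrow(p))) {
        shape <- pmax(p[j, ], 1e-8) * conc
        draw <- stats::rgamma(length(shape), shape = shape)
        if (sum(draw) <= 0) draw <- shape
        p[j, ] <- row_norm(draw / sum(draw), floor = 1e-5)
      }
      cpts[[v]]$prob <- p
    }
  })
  rt_network(base$edges, cpts, base$schema)
}

#' Mean total-variation distance between two networks' CPT rows
#'
#' @param net1,net2 two [rt_network()]s sharing structure and states.
#' @return Mean over all CPT rows of `0.5 * sum(|p - q|)`.
#' @export
mean_row_tv <- function(net1, net2) {
  tv <- unlist(lapply(net1$nodes, function(v) {
    a <- net1$cpts[[v]]$prob; b <- net2$cpts[[v]]$prob
    0.5 * rowSums(abs(a - b))
  }))
  mean(tv)
}

#' @export
print.rt_clinic_profile <- function(x, ...) {
  cat("<rt_clinic_profile> ", x$clinic_id, ": ", length(x$ground_truth$nodes),
      " variables; inapplicable: ",
      if (length(x$inapplicable)) paste(x$inapplicable, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Default three-clinic profiles
#'
#' Three synthetic clinics derived from [base_network()]. Clinic A does not
#' record wedge or tolerance-table settings, clinic B cannot extract bolus;
#' clinic C records everything.
#'
#' @inheritParams build_profiles
#' @export
default_profiles <- function(divergence = 1.5, seed = 1L, size_hint = 2000L) {
  build_profiles(base_network(), divergence = divergence, seed = seed,
                 size_hint = size_hint)
}

#' Sample a synthetic cohort from a clinic profile
#'
#' Ancestral sampling from the profile's ground-truth network, after which
#' structurally inapplicable variables are removed and per-variable
#' missing-at-random masking is applied.
#'
#' @param profile an `rt_clinic_profile`.
#' @param n number of plans (>= 0).
#' @param seed integer seed.
#' @return A cohort tibble (`plan_id`, `clinic`, one column per variable).
#' @export
sample_plans <- function(profile, n = profile$size_hint, seed = 1L) {
  stopifnot(n >= 0)
  net <- profile$ground_truth
  schema <- net$schema
  if (n == 0) {
    out <- tibble::as_tibble(c(list(plan_id = character(0), clinic = character(0)),
                               setNames(rep(list(character(0)), length(net$nodes)),
                                        net$nodes)))
    return(set_plan_schema(out, schema))
  }
  S <- with_seed(seed, sample_states(net, n))
  out <- tibble::tibble(plan_id = sprintf("%s_%05d", profile$clinic_id, seq_len(n)),
                        clinic = profile$clinic_id)
  for (v in net$nodes) out[[v]] <- net$states[[v]][S[, v]]
  for (v in profile$inapplicable) out[[v]] <- NA_character_
  miss <- profile$missingness
  if (length(miss)) {
    mask <- with_seed(derive_seed(seed, 7L), {
      lapply(intersect(names(miss), net$nodes), function(v)
        runif(n) < miss[[v]])
    })
    for (k in seq_along(intersect(names(miss), net$nodes))) {
      v <- intersect(names(miss), net$nodes)[k]
      out[[v]][mask[[k]]] <- NA_character_
    }
  }
  set_plan_schema(out, schema)
}

# vectorized ancestral sampling; returns an n x nodes integer matrix
sample_states <- function(net, n) {
  S <- matrix(NA_integer_, nrow = n, ncol = length(net$nodes),
              dimnames = list(NULL, net$nodes))
  for (v in topological_order(net$edges, net$nodes)) {
    cp <- net$cpts[[v]]
    cum <- t(apply(cp$prob, 1, cumsum))
    rows <- if (length(cp$parents)) {
      parent_combo_index(net, v, S[, cp$parents, drop = FALSE])
    } else rep.int(1L, n)
    u <- runif(n)
    pick <- rowSums(cum[rows, , drop = FALSE] < u) + 1L
    S[, v] <- pmin(pick, ncol(cp$prob))
  }
  S
}
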