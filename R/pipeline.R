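# End-to-end orchestration: synthetic study -> trip segmentation ->
# behavioural annotation -> tactic classification -> ODBA -> weather
# covariates -> binomial GLMM with repeatability and conditional modes ->
# fitness correlates, with a ground-truth comparison at the end.

PIPELINE_STAGES <- c("select_k", "odba", "descriptor_lmms", "reaction_norms",
                     "fitness")

#' Run the full foraging-tactic analysis on a synthetic study
#'
#' Generates a study from `config`, segments each individual's fixes into
#' foraging trips (trips start and end at the nest buffer), annotates fixes
#' with behavioural modes (one clustering per individual, pooled across its
#' trips; individuals with too few fixes borrow a global model), smooths the
#' labels, classifies trips into SF/DF by k-means on the behaviour profiles,
#' computes per-trip ODBA and weather covariates, fits the binomial GLMM of
#' tactic choice (single-step pruning of sex-by-weather interactions),
#' estimates adjusted repeatability and the individual conditional modes,
#' and correlates individual tendency with condition and fitness proxies.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @param stages Optional stages to run, any of
#'   `c("select_k", "odba", "descriptor_lmms", "reaction_norms", "fitness")`;
#'   the core chain (segment, annotate, classify, model) always runs.
#' @param nagq Quadrature nodes for the tactic GLMM.
#' @param n_sim Simulation draws for the conditional-mode SDs.
#' @param B Shuffles for the fitness randomization tests.
#' @param embc_pooling `"per_individual"` (default) or `"global"` behaviour
#'   clustering.
#' @param verbose Print stage progress.
#' @return A list of class `forage_report`; see the elements `trips`,
#'   `tactics`, `glmm`, `repeatability`, `modes`, `fitness` and
#'   `truth_check`.
#' @export
run_pipeline <- function(config = sim_config(), seed = NULL,
                         stages = PIPELINE_STAGES, nagq = 15, n_sim = 10000,
                         B = 9999, embc_pooling = c("per_individual", "global"),
                         verbose = FALSE) {
  embc_pooling <- match.arg(embc_pooling)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("simulate: seed %d", config$seed)
  study <- simulate_study(config)
  nests <- study$nest_coords

  say("segment: %d fixes", nrow(study$fixes))
  trips <- list(); trip_fix_rows <- list()
  for (i in seq_len(nrow(nests))) {
    id <- nests$individual_id[i]
    nest <- c(lat = nests$lat[i], lon = nests$lon[i])
    fx <- study$fixes[study$fixes$individual_id == id, , drop = FALSE]
    segs <- segment_trips(fx, nest, buffer_m = config$buffer_m,
                          tz_offset_h = config$tz_offset_h,
                          include_bounds = TRUE)
    for (s in segs) {
      desc <- trip_descriptors(s, nest)
      stage <- assign_stage(as.Date(s$t[1] + config$tz_offset_h * 3600),
                            study$nests[study$nests$individual_id == id, ])
      k <- length(trips) + 1
      trips[[k]] <- data.frame(
        trip_id = sprintf("%s_S%03d", id, attr(s, "trip_seq")),
        individual_id = id, stage = stage,
        dep_t = s$t[1], ret_t = s$t[nrow(s)],
        duration_h = desc$duration_h, length_km = desc$length_km,
        max_distance_km = desc$max_distance_km, tortuosity = desc$tortuosity,
        n_fixes = desc$n_fixes, incomplete = attr(s, "incomplete"))
      trip_fix_rows[[k]] <- fx$fix_id[attr(s, "fix_rows")]
    }
  }
  trips <- do.call(rbind, trips)
  say("segment: %d trips", nrow(trips))

  say("annotate: behavioural modes (%s)", embc_pooling)
  ann <- annotate_behaviours(study, trips, trip_fix_rows, pooling = embc_pooling)

  say("classify: trip profiles and k-means")
  prof <- t(vapply(seq_len(nrow(trips)), function(k) {
    trip_profile(ann$smoothed[[k]])
  }, numeric(4)))
  colnames(prof) <- c("perch", "intensive_search", "extensive_search", "relocation")
  consensus <- NULL
  if ("select_k" %in% stages) {
    consensus <- select_k(prof, seed = sub_seed(config$seed, 11))
    say("classify: consensus k = %d", consensus$k)
  }
  tac <- kmeans_tactics(prof, k = 2, seed = sub_seed(config$seed, 12))
  trips$tactic <- tac$tactic
  trips$tactic_df <- as.integer(tac$tactic == "DF")

  odba_df <- NULL
  if ("odba" %in% stages) {
    say("odba: %d trips at %g Hz", nrow(trips), config$acc_rate)
    odba_vals <- vapply(seq_len(nrow(trips)), function(k) {
      beh <- study$truth$fix_behaviour[trip_fix_rows[[k]]]
      acc <- simulate_acc_stream(beh, config, seed = sub_seed(config$seed, 100 + k))
      sp <- static_dynamic_split(acc, rate_hz = config$acc_rate, window_s = 1)
      mean(odba(sp$dynamic))
    }, numeric(1))
    trips$trip_odba_g <- odba_vals
    odba_df <- data.frame(trip_id = trips$trip_id, trip_odba_g = odba_vals,
                          n_samples = trips$n_fixes * config$fix_interval *
                            config$acc_rate)
  }

  say("weather: trip direction and wind components")
  wx <- lapply(seq_len(nrow(trips)), function(k) {
    id <- trips$individual_id[k]
    nr <- nests[nests$individual_id == id, ]
    nest <- c(lat = nr$lat, lon = nr$lon)
    fxk <- study$fixes[trip_fix_rows[[k]], ]
    td <- suppressWarnings(trip_direction(fxk, nest))
    wind_components(trips$dep_t[k], trips$ret_t[k], td, study$weather,
                    wind_dir_from = TRUE)
  })
  trips$td_deg <- vapply(seq_len(nrow(trips)), function(k) {
    id <- trips$individual_id[k]
    nr <- nests[nests$individual_id == id, ]
    fxk <- study$fixes[trip_fix_rows[[k]], ]
    suppressWarnings(trip_direction(fxk, c(lat = nr$lat, lon = nr$lon)))
  }, numeric(1))
  trips$solar <- vapply(wx, `[[`, numeric(1), "solar_wm2")
  trips$rain_present <- vapply(wx, function(w) as.numeric(w$rain_present), numeric(1))
  trips$twc <- vapply(wx, `[[`, numeric(1), "twc_ms")
  trips$cwc <- vapply(wx, `[[`, numeric(1), "cwc_ms")
  trips$time_arable <- vapply(seq_len(nrow(trips)), function(k) {
    fxk <- study$fixes[trip_fix_rows[[k]], ]
    suppressWarnings(habitat_time(fxk$habitat, ann$smoothed[[k]])[["arable"]])
  }, numeric(1))

  say("model: binomial GLMM of tactic choice")
  md <- trips
  md$sex <- study$adults$sex[match(md$individual_id, study$adults$individual_id)]
  md$stage01 <- as.integer(md$stage == "nestling_rearing")
  md$year <- factor(format(md$dep_t + config$tz_offset_h * 3600, "%Y"))
  multi <- names(table(md$individual_id))[table(md$individual_id) >= 2]
  md <- md[md$individual_id %in% multi, ]          # single-trip birds excluded
  md <- md[stats::complete.cases(md[, c("solar", "rain_present", "twc", "cwc",
                                        "time_arable")]), ]
  for (v in c("solar", "rain_present", "twc", "cwc", "time_arable", "stage01",
              "sex")) {
    md[[paste0("z_", v)]] <- zscore(md[[v]])
  }
  weather_z <- c("z_solar", "z_rain_present", "z_twc", "z_cwc")
  controls <- c("z_time_arable", "z_stage01", "z_sex",
                if (nlevels(md$year) > 1) "year")
  pruned <- backward_prune_interactions(
    response = "tactic_df", weather_vars = weather_z, controls = controls,
    sex_var = "z_sex", id_var = "individual_id", data = md, nagq = nagq)
  glmm <- pruned$final
  rpt <- adjusted_repeatability(glmm)
  modes <- conditional_modes(glmm, n_sim = n_sim,
                             seed = sub_seed(config$seed, 21))
  effect_r <- vapply(c(weather_z, "z_stage01"), function(term) {
    if (term %in% glmm$beta$term) effect_size_r(glmm, term) else NA_real_
  }, numeric(1))

  norms <- NULL
  if ("reaction_norms" %in% stages) {
    say("model: behavioural reaction norms")
    norms <- lapply(weather_z, function(wv) {
      res <- tryCatch(random_slope_model("tactic_df", wv,
                                         setdiff(c(controls), wv),
                                         "individual_id", md),
                      error = function(e) NULL)
      if (is.null(res)) return(data.frame(weather_var = wv, chi2 = NA, df = 2,
                                          p = NA, sigma2_slope = NA))
      data.frame(weather_var = wv, chi2 = res$lrt$chi2, df = res$lrt$df,
                 p = res$lrt$p, sigma2_slope = res$sigma2_slope)
    })
    norms <- do.call(rbind, norms)
  }

  desc_lmms <- NULL
  if ("descriptor_lmms" %in% stages) {
    say("model: trip-descriptor LMMs")
    dd <- md[!md$incomplete, ]
    resp <- c("duration_h", "length_km", "max_distance_km", "tortuosity",
              if ("trip_odba_g" %in% names(dd)) "trip_odba_g")
    desc_lmms <- lapply(resp, function(r) {
      f <- stats::as.formula(paste(r, "~ tactic_df + (1 | individual_id)"))
      fit <- fit_lmm(f, dd)
      est <- fit$beta[fit$beta$term == "tactic_df", ]
      data.frame(response = r, estimate = est$estimate, ci_lo = est$ci_lo,
                 ci_hi = est$ci_hi,
                 f_value = fit$anova["tactic_df", "F value"],
                 p = fit$anova["tactic_df", "Pr(>F)"],
                 r2_marginal = fit$r2[["marginal"]],
                 r2_conditional = fit$r2[["conditional"]])
    })
    desc_lmms <- do.call(rbind, desc_lmms)
  }

  fitness <- NULL
  if ("fitness" %in% stages) {
    say("fitness: condition and fitness correlates")
    fitness <- fitness_correlates(study, trips, modes, B = B,
                                  seed = sub_seed(config$seed, 31))
  }

  say("truth check")
  truth_check <- compare_to_truth(study, trips, glmm, modes)

  structure(list(
    study = study, trips = trips, profiles = prof, consensus = consensus,
    tactic_centers = attr(tac, "centers"), odba = odba_df,
    glmm_initial = pruned$initial, glmm = glmm,
    dropped_interactions = pruned$dropped,
    repeatability = rpt, modes = modes, effect_size_r = effect_r,
    reaction_norms = norms, descriptor_lmms = desc_lmms, fitness = fitness,
    truth_check = truth_check,
    n_trips = nrow(trips), prop_df = mean(trips$tactic_df),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "forage_report")
}

# per-individual (or global) behaviour clustering over the trips' fixes
annotate_behaviours <- function(study, trips, trip_fix_rows, pooling, min_pts = 50) {
  metrics <- lapply(trip_fix_rows, function(rows) {
    fxk <- study$fixes[rows, ]
    step_metrics(fxk)
  })
  ids <- unique(trips$individual_id)
  global_model <- NULL
  get_global <- function() {
    if (is.null(global_model)) {
      sp <- unlist(lapply(metrics, `[[`, "speed"))
      tu <- unlist(lapply(metrics, `[[`, "turn"))
      global_model <<- embc_fit(sp, tu)
    }
    global_model
  }
  models <- list()
  for (id in ids) {
    ks <- which(trips$individual_id == id)
    sp <- unlist(lapply(metrics[ks], `[[`, "speed"))
    tu <- unlist(lapply(metrics[ks], `[[`, "turn"))
    n_ok <- sum(stats::complete.cases(cbind(sp, tu)))
    models[[id]] <- if (pooling == "global" || n_ok < min_pts) get_global()
    else embc_fit(sp, tu)
  }
  raw <- vector("list", nrow(trips))
  smoothed <- vector("list", nrow(trips))
  for (k in seq_len(nrow(trips))) {
    m <- models[[trips$individual_id[k]]]
    lab <- embc_label(m, metrics[[k]]$speed, metrics[[k]]$turn)
    # first/last fixes lack turn: inherit the nearest labelled neighbour
    mode <- lab$mode
    post <- lab$posterior
    na_idx <- which(is.na(mode))
    lab_idx <- which(!is.na(mode))
    if (length(lab_idx) && length(na_idx)) {
      for (j in na_idx) {
        nb <- lab_idx[which.min(abs(lab_idx - j))]
        mode[j] <- mode[nb]
        post[j, ] <- post[nb, ]
      }
    }
    raw[[k]] <- mode
    smoothed[[k]] <- smooth_labels(mode, post, window = 5)
  }
  list(models = models, raw = raw, smoothed = smoothed)
}

# condition/fitness proxies joined to individual tendency
fitness_correlates <- function(study, trips, modes, B = 9999, seed = 1) {
  ad <- study$adults
  ad$smi <- as.numeric(scaled_mass_index(ad$body_mass, ad$keel))
  ad$tendency <- modes$mode[match(ad$individual_id, modes$individual)]
  ad$tendency_sd <- modes$sd[match(ad$individual_id, modes$individual)]
  ad$dbmi <- vapply(ad$individual_id, function(id) {
    nl <- study$nestlings[study$nestlings$brood_id == id, ]
    if (nrow(nl) == 0) return(NA_real_)
    dbmi(nl$mass_first, nl$mass_second, nl$days_elapsed)
  }, numeric(1))
  ad$feeding_freq <- vapply(seq_len(nrow(ad)), function(i) {
    tk <- trips[trips$individual_id == ad$individual_id[i], ]
    if (nrow(tk) == 0) return(NA_real_)
    feeding_frequency(nrow(tk), ad$tracked_hours[i], tk$stage)
  }, numeric(1))
  ad$brood_size[ad$brood_size == 0] <- NA
  if (all(is.na(ad$tendency_sd) | ad$tendency_sd == 0)) {
    # singular random-intercept fit: no uncertainty to weight by
    warning("all conditional-mode SDs are zero: using equal weights")
    ad$tendency_sd <- 1
  }
  keep <- !is.na(ad$tendency) & !is.na(ad$tendency_sd) & ad$tendency_sd > 0
  correlate_tendency(ad[keep, ], B = B, seed = seed)
}

# recovery diagnostics against the generator's ground truth
compare_to_truth <- function(study, trips, glmm, modes) {
  tt <- study$truth$trips
  # match each segmented trip to the truth trip with the same individual and
  # overlapping time window
  match_idx <- vapply(seq_len(nrow(trips)), function(k) {
    cand <- which(tt$individual_id == trips$individual_id[k] &
                    tt$dep_t <= trips$ret_t[k] & tt$ret_t >= trips$dep_t[k])
    if (length(cand) == 0) return(NA_integer_)
    ov <- pmin(as.numeric(tt$ret_t[cand]), as.numeric(trips$ret_t[k])) -
      pmax(as.numeric(tt$dep_t[cand]), as.numeric(trips$dep_t[k]))
    cand[which.max(ov)]
  }, integer(1))
  ok <- !is.na(match_idx)
  tactic_acc <- mean(trips$tactic[ok] == tt$tactic[match_idx[ok]])
  bt <- glmm$beta
  est <- function(term) {
    v <- bt$estimate[bt$term == term]
    if (length(v)) v else NA_real_
  }
  sign_hat <- c(solar = est("z_solar"), cwc = est("z_cwc"),
                stage = est("z_stage01"))
  truth_beta <- study$truth$true_params$beta[c("solar", "cwc", "stage")]
  ind <- study$truth$individual
  tend_cor <- if (stats::sd(modes$mode) > 0) {
    stats::cor(modes$mode,
               ind$intercept[match(modes$individual, ind$individual_id)])
  } else NA_real_
  list(n_trips_matched = sum(ok), tactic_accuracy = tactic_acc,
       beta_hat = sign_hat, beta_true = truth_beta,
       signs_recovered = all(sign(sign_hat) == sign(truth_beta), na.rm = FALSE),
       tendency_cor = tend_cor)
}

#' @export
print.forage_report <- function(x, ...) {
  cat("Foraging-tactic analysis report\n")
  cat(sprintf("  %d trips from %d individuals; %.0f%% dynamic foraging\n",
              x$n_trips, length(unique(x$trips$individual_id)),
              100 * x$prop_df))
  if (!is.null(x$consensus)) {
    cat(sprintf("  consensus cluster number: %d\n", x$consensus$k))
  }
  if (!is.null(x$odba)) {
    m <- tapply(x$trips$trip_odba_g, x$trips$tactic, mean, na.rm = TRUE)
    cat(sprintf("  mean ODBA: SF %.3f g, DF %.3f g\n", m["SF"], m["DF"]))
  }
  cat(sprintf("  R_adj = %.3f (LRT chi2 = %.2f, p = %.3g)\n",
              x$repeatability$r_adj, x$repeatability$lrt_chi2,
              x$repeatability$p))
  cat("  final GLMM coefficients:\n")
  tab <- x$glmm$beta[, c("term", "estimate", "ci_lo", "ci_hi")]
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$fitness)) {
    cat("  fitness correlates:\n")
    ft <- x$fitness
    ft[c("r_w", "p_rand")] <- lapply(ft[c("r_w", "p_rand")], round, 3)
    print(ft, row.names = FALSE)
  }
  cat(sprintf("  tactic-vs-truth accuracy: %.3f; all key signs recovered: %s\n",
              x$truth_check$tactic_accuracy, x$truth_check$signs_recovered))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
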