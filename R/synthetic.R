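#' Configuration for the synthetic multi-omics generator
#'
#' Collects and validates the parameters of the synthetic cohort: a
#' methylation matrix with block (module) correlation structure, survival
#' times generated under proportional hazards from a set of driver sites,
#' and matched expression-like platforms with attenuated survival signal.
#'
#' @param n_sites Number of CpG sites (default 2000).
#' @param n_samples Number of patients (default 300).
#' @param n_modules Number of co-methylated modules (default 10).
#' @param module_size Sites per module (default 50); the remaining sites
#'   are unstructured noise.
#' @param correlation_strength Share of a module site's latent variance
#'   carried by the module factor, in (0, 1) (default 0.8).
#' @param n_drivers Number of prognostic driver sites, placed inside
#'   modules (default 20).
#' @param driver_effect Log-hazard per unit beta value of a driver site
#'   (default 2.0).
#' @param censoring_rate Target fraction of censored patients (default 0.4).
#' @param baseline_hazard Baseline hazard per day for a patient of average
#'   risk (default 5e-4, i.e. median survival around 3.8 years).
#' @param platform_profiles Named list of per-platform profiles for
#'   [generate_platforms()], each a list with \code{n_features},
#'   \code{attenuation} (strength of the driver features' coupling to the
#'   latent risk) and \code{bounded} (TRUE for beta-value-like matrices in
#'   \[0,1\], FALSE for unbounded expression values).
#' @param seed Master seed; everything the generator emits is a
#'   deterministic function of the config.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_sites = 2000, n_samples = 300, n_modules = 10,
                         module_size = 50, correlation_strength = 0.8,
                         n_drivers = 20, driver_effect = 2.0,
                         censoring_rate = 0.4, baseline_hazard = 5e-4,
                         platform_profiles = list(
                           methylation = list(n_features = 1000, attenuation = 1.0, bounded = TRUE),
                           mrna = list(n_features = 1000, attenuation = 0.5, bounded = FALSE),
                           mirna = list(n_features = 1000, attenuation = 0.2, bounded = FALSE)),
                         seed = 1) {
  if (n_sites < 1 || n_samples < 1 || n_modules < 1 || module_size < 1 || n_drivers < 0)
    stopf("counts must be positive")
  if (n_modules * module_size > n_sites)
    stopf("n_modules * module_size (%d) exceeds n_sites (%d)", n_modules * module_size, n_sites)
  if (!(correlation_strength > 0 && correlation_strength < 1))
    stopf("correlation_strength must be in (0, 1)")
  if (censoring_rate < 0 || censoring_rate >= 1) stopf("censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (n_drivers > n_modules * module_size)
    stopf("n_drivers (%d) exceeds the number of module sites", n_drivers)
  structure(list(n_sites = n_sites, n_samples = n_samples, n_modules = n_modules,
                 module_size = module_size, correlation_strength = correlation_strength,
                 n_drivers = n_drivers, driver_effect = driver_effect,
                 censoring_rate = censoring_rate, baseline_hazard = baseline_hazard,
                 platform_profiles = platform_profiles, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic methylation matrix with module structure
#'
#' Module sites share a per-sample latent Gaussian factor; each member
#' site's latent value mixes the factor (weight sqrt(correlation_strength))
#' with independent noise, and beta values are the inverse logit of the
#' latent value plus a per-site baseline, which guarantees \[0, 1\].
#' Remaining sites are independent noise. Driver sites are spread evenly
#' across the modules, so they sit inside correlated blocks — the premise
#' under which prognostic sites acquire high network degree.
#'
#' @param cfg A [synth_config()].
#' @return list with \code{m} (methylation matrix) and \code{truth}
#'   (list: module (named integer, 0 = unstructured), drivers (site ids),
#'   driver_coefficients, latent_risk per sample).
#' @export
generate_methylation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    ns <- cfg$n_sites
    np <- cfg$n_samples
    sites <- sprintf("cg%06d", seq_len(ns))
    samples <- sprintf("P%04d", seq_len(np))
    module <- integer(ns)
    names(module) <- sites
    n_structured <- cfg$n_modules * cfg$module_size
    module[seq_len(n_structured)] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)

    s <- cfg$correlation_strength
    factors <- matrix(stats::rnorm(cfg$n_modules * np), nrow = cfg$n_modules)
    mu <- stats::runif(ns, -1.5, 1.5)
    z <- matrix(stats::rnorm(ns * np), nrow = ns)
    idx <- which(module > 0)
    z[idx, ] <- sqrt(s) * factors[module[idx], , drop = FALSE] +
      sqrt(1 - s) * z[idx, , drop = FALSE]
    m <- stats::plogis(mu + 1.5 * z)
    dimnames(m) <- list(sites, samples)

    # drivers: spread across modules so each correlated block carries signal
    drv_idx <- integer(0)
    if (cfg$n_drivers > 0) {
      per_mod <- ceiling(cfg$n_drivers / cfg$n_modules)
      cand <- unlist(lapply(seq_len(cfg$n_modules), function(mm)
        which(module == mm)[seq_len(per_mod)]))
      drv_idx <- sort(cand[seq_len(cfg$n_drivers)])
    }
    drivers <- sites[drv_idx]
    coefs <- stats::setNames(rep(cfg$driver_effect, length(drivers)), drivers)
    latent <- if (length(drivers) > 0)
      colSums(m[drivers, , drop = FALSE] * cfg$driver_effect) else
      stats::setNames(rep(0, np), samples)
    list(m = m,
         truth = list(module = module, drivers = drivers,
                      driver_coefficients = coefs,
                      latent_risk = stats::setNames(as.numeric(latent), samples)))
  })
}

# Calibrate the uniform censoring window so that roughly `rate` of the
# event times fall after their censoring time: solves E[min(T/w, 1)] = rate.
censoring_window <- function(event_times, rate) {
  f <- function(w) mean(pmin(event_times / w, 1)) - rate
  upper <- max(event_times) * 2
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, lower = min(event_times) * 1e-6, upper = upper)$root
}

#' Generate survival outcomes from driver sites
#'
#' Event times are exponential with per-patient hazard
#' baseline_hazard * exp(linear predictor), where the linear predictor sums
#' driver_effect times the beta value over the driver sites and is centered
#' at its cohort mean (so baseline_hazard is the hazard of an average
#' patient). Censoring times are independent uniform over a window
#' calibrated to hit the target censoring rate approximately.
#'
#' @param m Methylation matrix containing the driver sites.
#' @param truth Ground truth from [generate_methylation()].
#' @param cfg The [synth_config()] used.
#' @return Clinical table data.frame (sample, time_days, event).
#' @export
generate_survival <- function(m, truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  missing <- setdiff(truth$drivers, rownames(m))
  if (length(missing) > 0) stopf("driver sites absent from matrix: %s", missing[1])
  with_seed(cfg$seed + 1L, {
    np <- ncol(m)
    lp <- if (length(truth$drivers) > 0)
      colSums(m[truth$drivers, , drop = FALSE] * truth$driver_coefficients[truth$drivers])
    else rep(0, np)
    hazard <- cfg$baseline_hazard * exp(lp - mean(lp))
    t_event <- stats::rexp(np, rate = hazard)
    if (cfg$censoring_rate <= 0) {
      time <- t_event
      event <- rep(1L, np)
    } else {
      w <- censoring_window(t_event, cfg$censoring_rate)
      c_time <- stats::runif(np, 0, w)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    }
    data.frame(sample = colnames(m),
               time_days = pmax(time, 1e-3),
               event = event,
               stringsAsFactors = FALSE)
  })
}

#' Generate matched multi-platform data with a shared clinical table
#'
#' Emulates matched methylation / mRNA / miRNA cohorts: a per-patient
#' latent risk drives both the survival outcome and, with platform-specific
#' strength, the first n_drivers features of every platform. A platform's
#' \code{attenuation} a couples its driver features to the latent risk as
#' (a * risk + noise) / sqrt(a^2 + 1); attenuation 1 is a strong, consistent
#' signal (methylation-like), small attenuation a weak, noisy one
#' (miRNA-like). Bounded platforms are squashed through the inverse logit
#' into \[0, 1\]; unbounded ones stay Gaussian. Platforms with identical
#' profiles are statistically exchangeable by construction.
#'
#' @param cfg A [synth_config()]; uses \code{platform_profiles},
#'   \code{n_drivers}, \code{censoring_rate}, \code{baseline_hazard} and
#'   \code{n_samples}.
#' @return list with \code{platforms} (named list of feature matrices),
#'   \code{clinical} (shared clinical table), and \code{truth}
#'   (latent risk and per-platform driver feature ids).
#' @export
generate_platforms <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(cfg$platform_profiles) < 2) stopf("need profiles for at least 2 platforms")
  np <- cfg$n_samples
  samples <- sprintf("P%04d", seq_len(np))
  latent <- with_seed(cfg$seed + 2L, stats::rnorm(np))

  clinical <- with_seed(cfg$seed + 3L, {
    hazard <- cfg$baseline_hazard * exp(latent)
    t_event <- stats::rexp(np, rate = hazard)
    if (cfg$censoring_rate <= 0) {
      time <- t_event; event <- rep(1L, np)
    } else {
      w <- censoring_window(t_event, cfg$censoring_rate)
      c_time <- stats::runif(np, 0, w)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    }
    data.frame(sample = samples, time_days = pmax(time, 1e-3), event = event,
               stringsAsFactors = FALSE)
  })

  platforms <- list()
  drivers <- list()
  for (pi in seq_along(cfg$platform_profiles)) {
    name <- names(cfg$platform_profiles)[pi]
    prof <- cfg$platform_profiles[[pi]]
    platforms[[name]] <- with_seed(cfg$seed + 10L + pi, {
      nf <- prof$n_features
      a <- prof$attenuation
      feats <- sprintf("%s_f%05d", name, seq_len(nf))
      z <- matrix(stats::rnorm(nf * np), nrow = nf, dimnames = list(feats, samples))
      nd <- min(cfg$n_drivers, nf)
      if (nd > 0)
        z[seq_len(nd), ] <- (a * matrix(latent, nrow = nd, ncol = np, byrow = TRUE) +
                               z[seq_len(nd), , drop = FALSE]) / sqrt(a^2 + 1)
      if (isTRUE(prof$bounded)) stats::plogis(1.5 * z) else z
    })
    drivers[[name]] <- rownames(platforms[[name]])[seq_len(min(cfg$n_drivers, nrow(platforms[[name]])))]
  }
  list(platforms = platforms,
       clinical = clinical,
       truth = list(latent_risk = stats::setNames(latent, samples),
                    drivers = drivers))
}
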