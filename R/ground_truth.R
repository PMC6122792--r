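#' Ground-truth configuration for the synthetic survivor cohort
#'
#' Bundles everything the synthetic-cohort generator needs: the published
#' network structure for the chosen variant, the published regression
#' coefficients for every edge, and per-variable marginal targets (mean/SD
#' for continuous variables, prevalence for binary ones) taken from the
#' cohort characteristics table. Log-insulin and log-CRP targets are the
#' obese / non-obese group means and SDs blended by the obesity weight
#' `P(BMI >= 30)` under `Normal(31.1, 4.9)`, since the characteristics table
#' reports only medians and IQRs for the raw biomarkers. Alcohol intake and
#' MVPA use log-normal marginals matched to the printed statistics so that
#' strictly positive skewed measures never go negative.
#'
#' @param variant `"total_pa"` (19 variables) or `"mvpa_sedentary"` (20).
#' @param n Default cohort size for downstream sampling (study size 333).
#' @param seed Integer seed recorded in the config and used for calibration
#'   pilots and sampling unless overridden.
#' @param truncate_bmi_at_25 If `TRUE`, resample BMI draws below 25 (the
#'   cohort enrolled only overweight or obese women). Defaults to `FALSE`:
#'   untruncated moments reproduce the published conditional group means.
#' @return An object of class `bn_ground_truth_config`.
#' @export
ground_truth_config <- function(variant = c("total_pa", "mvpa_sedentary"),
                                n = 333, seed = 20180904,
                                truncate_bmi_at_25 = FALSE) {
  variant <- match.arg(variant)
  schema <- cohort_schema(variant)
  structure_tbl <- ground_truth_edges(variant)
  graph <- bn_dag(schema$name, structure_tbl[c("from", "to")])
  marg <- ground_truth_marginals(variant)
  stopifnot(setequal(marg$node, schema$name))
  structure(list(variant = variant, schema = schema, structure = graph,
                 coefficients = structure_tbl, target_marginals = marg,
                 n = n, seed = seed,
                 truncate_bmi_at_25 = truncate_bmi_at_25),
            class = "bn_ground_truth_config")
}

#' @export
print.bn_ground_truth_config <- function(x, ...) {
  cat("<ground truth config: ", x$variant, ", ",
      length(x$structure$nodes), " variables, ",
      nrow(x$structure$edges), " edges, n = ", x$n, ">\n", sep = "")
  invisible(x)
}

# published edge coefficients; `coef` is a linear slope (continuous child)
# or a log-odds ratio (binary child)
ground_truth_edges <- function(variant) {
  e <- function(from, to, coef, se) {
    tibble::tibble(from = from, to = to, coef = coef, se = se)
  }
  shared <- dplyr::bind_rows(
    e("Insomnia", "Depression", 1.000, 0.257),
    e("Insomnia", "Sleep1", 10.641, 0.915),
    e("Depression", "Sleep1", 1.710, 0.845),
    e("Depression", "Arthritis", 0.704, 0.239),
    e("Depression", "Sleep2", 3.489, 0.741),
    e("Sleep1", "Sleep2", 0.665, 0.042),
    e("BMI", "QOLp", -0.689, 0.176),
    e("Sleep2", "QOLp", -0.921, 0.096),
    e("Arthritis", "QOLp", -7.439, 1.740),
    e("Depression", "QOLm", -7.029, 1.717),
    e("Sleep2", "QOLm", -1.060, 0.094),
    e("BMI", "loginsulin", 0.039, 0.006),
    e("BMI", "logcrp", 0.093, 0.012)
  )
  if (variant == "total_pa") {
    dplyr::bind_rows(
      shared,
      e("Smoke", "BMI", 1.157, 0.551),
      e("Arthritis", "BMI", 1.524, 0.555),
      e("Age", "PA", -4.563, 0.845),
      e("Sleep2", "PA", -1.905, 0.659),
      e("loginsulin", "PA", -43.926, 11.188)
    )
  } else {
    dplyr::bind_rows(
      shared,
      e("Smoke", "BMI", 1.196, 0.557),
      e("Arthritis", "Sedentary", -11.706, 7.178),
      e("MVPA", "Sedentary", -1.788, 0.213)
    )
  }
}

# obesity weight under the BMI marginal: P(BMI >= 30 | N(31.1, 4.9))
obesity_weight <- function() stats::pnorm((31.1 - 30) / 4.9)

ground_truth_marginals <- function(variant) {
  w <- obesity_weight()
  m <- function(node, dist, mean = NA, sd = NA, prevalence = NA) {
    tibble::tibble(node = node, dist = dist, mean = mean, sd = sd,
                   prevalence = prevalence)
  }
  # MVPA log-normal matched to mean 17.5, SD 17.3
  mv_s2 <- log(1 + (17.3 / 17.5)^2)
  base <- dplyr::bind_rows(
    m("TumorStage", "normal", 1.69, 0.7443),     # moments of 48/35/17% stages
    m("YrsDXRND", "normal", 2.7, 2.0),
    m("Neighborhood", "normal", 3.1, 1.7),
    m("Alcohol", "lognormal", log(4), 1.0),      # median 4 drinks/month
    m("Coping", "normal", 4.2, 3.5),
    m("Education", "normal", 0.51, sqrt(0.51 * 0.49)),
    m("Age", "normal", 63, 6.9),
    m("Smoke", "bernoulli", prevalence = 0.45),
    m("Insomnia", "bernoulli", prevalence = 0.288),
    m("Depression", "bernoulli", prevalence = 0.408),
    m("Sleep1", "normal", 50.5, 8.8),
    m("Arthritis", "bernoulli", prevalence = 0.564),
    m("BMI", "normal", 31.1, 4.9),
    m("Sleep2", "normal", 46.9, 9.0),
    m("QOLp", "normal", 66.2, 18.7),
    m("QOLm", "normal", 73.6, 18.4),
    m("loginsulin", "normal", w * 6.29 + (1 - w) * 5.99,
      w * 0.50 + (1 - w) * 0.49),
    m("logcrp", "normal", w * 15.28 + (1 - w) * 14.56,
      w * 1.07 + (1 - w) * 1.05)
  )
  act <- if (variant == "total_pa") {
    m("PA", "normal", 273.1, 108.6)
  } else {
    dplyr::bind_rows(
      m("MVPA", "lognormal", log(17.5) - mv_s2 / 2, sqrt(mv_s2)),
      m("Sedentary", "normal", 471, 111)
    )
  }
  dplyr::bind_rows(base, act)
}

# mean/sd a marginal target implies on the data scale (lognormal converted)
target_moments <- function(row) {
  if (row$dist == "lognormal") {
    mu <- exp(row$mean + row$sd^2 / 2)
    list(mean = mu, sd = mu * sqrt(exp(row$sd^2) - 1))
  } else if (row$dist == "bernoulli") {
    list(mean = row$prevalence, sd = sqrt(row$prevalence * (1 - row$prevalence)))
  } else {
    list(mean = row$mean, sd = row$sd)
  }
}

#' Calibrate intercepts and residual variances against marginal targets
#'
#' Turns a [ground_truth_config()] into a fully parameterized generative
#' network (`bn_fit`). Nodes are processed in topological order. For each
#' linear-Gaussian node, a Monte-Carlo pilot sample of its parents (drawn
#' from the already-calibrated sub-network) gives the mean and variance of
#' the linear predictor; the intercept then centers the node on its target
#' mean and the residual SD absorbs the unexplained part of the target
#' variance, `residual_sd = sqrt(target_var - explained_var)`, floored at 1%
#' of the target variance. If the explained variance reaches the target
#' variance the node is reported as infeasible. For each logistic node the
#' intercept is solved by one-dimensional root finding so the implied
#' marginal prevalence matches the target (exactly, via the parent's target
#' prevalence, for a single binary parent; otherwise against the pilot
#' draws, to within 1e-4).
#'
#' @param config A [ground_truth_config()].
#' @param pilot_draws Pilot-sample size for explained-variance estimation
#'   (default 50000).
#' @param seed Calibration seed; defaults to the config seed.
#' @return A `bn_fit` ground-truth network (attribute `"calibration"` holds a
#'   per-node tibble of targets, explained variance, and intercepts).
#' @export
calibrate_network <- function(config, pilot_draws = 50000, seed = NULL) {
  stopifnot(inherits(config, "bn_ground_truth_config"))
  seed <- seed %||% config$seed
  graph <- config$structure
  marg <- config$target_marginals
  coefs <- config$coefficients
  order <- topo_sort(graph)
  locals <- list()
  audit <- list()
  # pilot matrix grown column by column in topological order
  pilot <- matrix(NA_real_, nrow = pilot_draws, ncol = 0)

  for (node in order) {
    row <- marg[marg$node == node, ]
    pa <- parents(graph, node)
    ce <- coefs[coefs$to == node, ]
    beta <- stats::setNames(ce$coef, ce$from)[pa]
    kind <- config$schema$kind[match(node, config$schema$name)]
    set.seed(substream_seed(seed, paste0("pilot:", node)))

    if (kind == "binary") {
      target_p <- row$prevalence
      if (!length(pa)) {
        cpd <- cpd_logistic(node, intercept = stats::qlogis(target_p))
      } else {
        if (length(pa) == 1 && all(pa %in% marg$node[marg$dist == "bernoulli"])) {
          # exact: parent marginal prevalence is itself a calibration target
          pp <- marg$prevalence[marg$node == pa]
          f <- function(a) {
            pp * stats::plogis(a + beta[[pa]]) +
              (1 - pp) * stats::plogis(a) - target_p
          }
        } else {
          lp0 <- as.vector(pilot[, pa, drop = FALSE] %*% beta)
          f <- function(a) mean(stats::plogis(a + lp0)) - target_p
        }
        a <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
        cpd <- cpd_logistic(node, pa, intercept = a, coefficients = beta)
      }
      draw <- stats::rbinom(pilot_draws, 1,
                            stats::plogis(cpd$intercept +
                              if (length(pa))
                                as.vector(pilot[, pa, drop = FALSE] %*% beta)
                              else 0))
      audit[[node]] <- tibble::tibble(node = node, form = "logistic",
                                      target = target_p,
                                      explained = NA_real_,
                                      intercept = cpd$intercept,
                                      residual_sd = NA_real_)
    } else if (row$dist == "lognormal") {
      if (length(pa)) bn_abort("lognormal marginals are only for root nodes")
      cpd <- cpd_lognormal(node, intercept = row$mean, residual_sd = row$sd)
      draw <- stats::rlnorm(pilot_draws, row$mean, row$sd)
      audit[[node]] <- tibble::tibble(node = node, form = "lognormal_root",
                                      target = target_moments(row)$mean,
                                      explained = 0, intercept = row$mean,
                                      residual_sd = row$sd)
    } else {
      target_var <- row$sd^2
      if (!length(pa)) {
        cpd <- cpd_linear(node, intercept = row$mean, residual_sd = row$sd)
        explained <- 0
        lp <- rep(0, pilot_draws)
      } else {
        lp <- as.vector(pilot[, pa, drop = FALSE] %*% beta)
        explained <- stats::var(lp)
        if (explained >= target_var) {
          bn_abort(paste0(
            "calibration infeasible for ", node, ": explained variance ",
            format(explained, digits = 4), " >= target variance ",
            format(target_var, digits = 4)),
            class = "behavnet_calibration_error")
        }
        resid_sd <- sqrt(max(target_var - explained, 0.01 * target_var))
        cpd <- cpd_linear(node, pa, intercept = row$mean - mean(lp),
                          coefficients = beta, residual_sd = resid_sd)
      }
      draw <- cpd$intercept + lp +
        stats::rnorm(pilot_draws, 0, cpd$residual_sd)
      if (node == "BMI" && isTRUE(config$truncate_bmi_at_25)) {
        low <- draw < 25
        while (any(low)) {
          draw[low] <- cpd$intercept + lp[low] +
            stats::rnorm(sum(low), 0, cpd$residual_sd)
          low <- draw < 25
        }
      }
      audit[[node]] <- tibble::tibble(node = node, form = cpd$form,
                                      target = row$mean, explained = explained,
                                      intercept = cpd$intercept,
                                      residual_sd = cpd$residual_sd %||% NA_real_)
    }
    locals[[node]] <- cpd
    pilot <- cbind(pilot, stats::setNames(data.frame(draw), node))
    colnames(pilot)[ncol(pilot)] <- node
    pilot <- as.matrix(pilot)
  }

  fit <- bn_fit(graph, locals, n = config$n)
  attr(fit, "calibration") <- dplyr::bind_rows(audit)
  attr(fit, "config") <- config
  fit
}
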