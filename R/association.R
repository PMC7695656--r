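#' Specification of a mixed-model analysis
#'
#' Defines outcome, exposures, covariate set, interactions, priors and
#' MCMC settings for [fit_logistic_mixed()] / [fit_bmi_lmm()]. The
#' `model1` covariate set is sex, baseline age, baseline education,
#' baseline physical activity, energy intake, alcohol intake and
#' follow-up time; `model2` adds BMI, baseline diabetes and baseline
#' hypertension. The diet-by-BMI interaction is only allowed with
#' `model2`. "Non-informative" priors are realized as wide normal priors
#' on coefficients (`prior_beta_sd`, default 10 on the internally
#' standardized covariate scale) and a weakly-informative half-normal on
#' the random-intercept SD (`prior_ri_scale`).
#'
#' @param outcome `"nafld"` (binary steatosis, logistic) or `"bmi"`
#'   (continuous, Gaussian).
#' @param exposures Character vector of score column names. A priori
#'   scores are conventionally fitted singly; the five a posteriori
#'   scores jointly.
#' @param covariates `"model1"`, `"model2"`, `"none"`, or an explicit
#'   character vector of covariate names.
#' @param interactions Subset of `c("diet_time", "diet_bmi")`.
#' @param prior_beta_sd,prior_ri_scale,prior_resid_scale Prior scales.
#' @param n_chains,n_adapt,n_burn,n_iter,thin MCMC settings.
#' @param seed Integer seed (per-chain RNGs are derived from it).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("nafld", "bmi"),
                       exposures,
                       covariates = "model1",
                       interactions = character(),
                       prior_beta_sd = 10,
                       prior_ri_scale = 2,
                       prior_resid_scale = 10,
                       n_chains = 2, n_adapt = 500, n_burn = 500,
                       n_iter = 1000, thin = 1, seed = 1L) {
  outcome <- match.arg(outcome)
  model1 <- c("female", "age", "education", "physical_activity",
              "energy", "alcohol", "time")
  model2 <- c(model1, "bmi", "diabetes", "hypertension")
  set_name <- if (is.character(covariates) && length(covariates) == 1 &&
                  covariates %in% c("model1", "model2", "none"))
    covariates else "custom"
  covs <- switch(set_name, model1 = model1, model2 = model2,
                 none = character(), custom = covariates)
  if (!all(interactions %in% c("diet_time", "diet_bmi")))
    stop("interactions must be among 'diet_time', 'diet_bmi'")
  if ("diet_bmi" %in% interactions && !"bmi" %in% covs)
    stop("'diet_bmi' interaction requires the model2 covariate set")
  if (outcome == "bmi") covs <- setdiff(covs, "bmi")
  structure(list(outcome = outcome, exposures = exposures,
                 covariates = covs, covariate_set = set_name,
                 interactions = interactions,
                 prior_beta_sd = prior_beta_sd,
                 prior_ri_scale = prior_ri_scale,
                 prior_resid_scale = prior_resid_scale,
                 n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
                 n_iter = n_iter, thin = thin, seed = as.integer(seed)),
            class = "model_spec")
}

#' Specification of the covariate imputation models
#'
#' Incomplete covariates are imputed simultaneously with the regression
#' coefficients: each gets a conditional model with the complete
#' `model2` covariates as predictors — linear for continuous, logistic
#' for binary, cumulative-logit for ordered categorical covariates.
#' Families are detected from the data at fit time unless fixed here.
#' Outcome and exposures are never imputed.
#'
#' @param families Optional named character vector fixing the family per
#'   covariate (`"normal"`, `"logistic"`, `"cumlogit"`).
#' @param predictors Optional character vector of predictor covariates
#'   (default: the complete covariates of the model2 set present in the
#'   data).
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(families = NULL, predictors = NULL) {
  structure(list(families = families, predictors = predictors),
            class = "imputation_spec")
}

cov_type <- function(name, x) {
  if (name %in% c("female", "diabetes", "hypertension", "smoking")) return("binary")
  if (name == "education") return("ordinal")
  u <- unique(x[!is.na(x)])
  if (all(u %in% 0:1)) "binary"
  else if (name %in% c("education") || (is.integer(x) && length(u) <= 5 &&
                                        min(u) == 1)) "ordinal"
  else "continuous"
}

prepare_model_data <- function(data, spec, imputation) {
  need <- c(spec$exposures, spec$covariates,
            if (spec$outcome == "nafld") "steatosis" else "bmi", "id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- data[order(data$id, if ("visit" %in% names(data)) data$visit else 0), ]
  y <- if (spec$outcome == "nafld") data$steatosis else data$bmi
  if (anyNA(y)) stop("the outcome may not contain missing values")
  # Gaussian outcomes are standardized for sampling and back-transformed
  y_mean <- 0; y_sd <- 1
  if (spec$outcome == "bmi") {
    y_mean <- mean(y); y_sd <- sd(y)
    if (y_sd == 0) y_sd <- 1
    y <- (y - y_mean) / y_sd
  }
  if (anyNA(data[spec$exposures])) stop("exposures may not contain missing values")
  subj <- match(data$id, unique(data$id))
  S <- max(subj)

  types <- vapply(spec$covariates, function(cv) cov_type(cv, data[[cv]]),
                  character(1))
  incomplete <- spec$covariates[vapply(spec$covariates,
                                       function(cv) anyNA(data[[cv]]), TRUE)]
  # incomplete covariates must be participant-constant (baseline variables)
  for (cv in incomplete) {
    cons <- tapply(data[[cv]], subj, function(v)
      length(unique(v[!is.na(v)])) <= 1 || all(is.na(v)))
    if (!all(cons)) stop("incomplete covariate '", cv,
                         "' is not participant-constant")
  }

  std <- function(x) {
    m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    list(z = (x - m) / s, mean = m, sd = s)
  }

  # ---- complete fixed-effect design (standardized continuous columns)
  terms <- "(Intercept)"; Xcols <- list(rep(1, nrow(data))); scales <- 1
  col_std <- list()   # standardized versions for building interactions
  add_col <- function(nm, z, sc) {
    terms <<- c(terms, nm); Xcols[[length(Xcols) + 1L]] <<- z
    scales <<- c(scales, sc)
  }
  for (cv in setdiff(spec$covariates, incomplete)) {
    if (types[[cv]] == "continuous") {
      s <- std(data[[cv]]); col_std[[cv]] <- s
      add_col(cv, s$z, 1 / s$sd)
    } else if (types[[cv]] == "binary") {
      add_col(cv, as.numeric(data[[cv]]), 1)
    } else {
      lev <- sort(unique(data[[cv]]))
      for (l in lev[-1]) add_col(paste0(cv, l), as.numeric(data[[cv]] == l), 1)
    }
  }
  for (ex in spec$exposures) {
    s <- std(data[[ex]]); col_std[[ex]] <- s
    add_col(ex, s$z, 1 / s$sd)
  }
  for (ia in spec$interactions) {
    mod <- if (ia == "diet_time") "time" else "bmi"
    if (mod %in% incomplete)
      stop("interaction modifier '", mod, "' may not be incomplete")
    if (!mod %in% names(col_std)) {
      if (!mod %in% names(data)) stop("missing column: ", mod)
      col_std[[mod]] <- std(data[[mod]])
    }
    for (ex in spec$exposures)
      add_col(paste0(ex, ":", mod), col_std[[ex]]$z * col_std[[mod]]$z,
              (1 / col_std[[ex]]$sd) * (1 / col_std[[mod]]$sd))
  }
  X <- do.call(cbind, Xcols)
  colnames(X) <- terms

  # ---- subject-level predictor matrix for imputation models
  model2 <- c("female", "age", "education", "physical_activity", "energy",
              "alcohol", "bmi", "diabetes", "hypertension")
  preds <- imputation$predictors
  if (is.null(preds))
    preds <- setdiff(intersect(model2, names(data)), incomplete)
  preds <- preds[!vapply(preds, function(cv) anyNA(data[[cv]]), TRUE)]
  base_idx <- !duplicated(subj)
  W <- matrix(1, S, 1)
  for (cv in preds) {
    x <- data[[cv]][base_idx]
    tp <- cov_type(cv, x)
    if (tp == "continuous") W <- cbind(W, std(x)$z)
    else if (tp == "binary") W <- cbind(W, as.numeric(x))
    else for (l in sort(unique(x))[-1]) W <- cbind(W, as.numeric(x == l))
  }

  # ---- incomplete covariates at subject level
  inc <- list()
  for (cv in incomplete) {
    fam <- if (!is.null(imputation$families) && cv %in% names(imputation$families))
      imputation$families[[cv]]
    else switch(types[[cv]], continuous = "normal", binary = "logistic",
                ordinal = "cumlogit")
    v <- tapply(data[[cv]], subj, function(z) {
      z <- z[!is.na(z)]; if (length(z)) z[1] else NA
    })
    v <- as.numeric(v[order(as.integer(names(v)))])
    entry <- list(name = cv, family = fam, miss = which(is.na(v)))
    if (fam == "normal") {
      s <- std(v)
      entry$values <- s$z; entry$mean <- s$mean; entry$sd <- s$sd
      entry$terms <- cv; entry$scales <- 1 / s$sd
    } else if (fam == "logistic") {
      entry$values <- v; entry$terms <- cv; entry$scales <- 1
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      if (length(lev) != 3)
        stop("cumulative-logit imputation implemented for 3 ordered levels; '",
             cv, "' has ", length(lev))
      entry$values <- match(v, lev)
      entry$levels <- lev
      entry$terms <- paste0(cv, lev[-1]); entry$scales <- c(1, 1)
    }
    inc[[cv]] <- entry
  }

  list(data = data, y = y, X = X, subj = subj, S = S, W = W,
       terms = terms, scales = scales, incomplete = inc, types = types,
       y_mean = y_mean, y_sd = y_sd)
}

build_jags_code <- function(spec, pd) {
  inc_terms <- vapply(pd$incomplete, function(e) {
    switch(e$family,
      normal = , logistic = sprintf(" + b_%s * v_%s[subj[j]]", e$name, e$name),
      cumlogit = sprintf(
        " + b_%s2 * equals(v_%s[subj[j]], 2) + b_%s3 * equals(v_%s[subj[j]], 3)",
        e$name, e$name, e$name, e$name))
  }, character(1))
  lhs <- if (spec$outcome == "nafld")
    "y[j] ~ dbern(p[j])\n    logit(p[j]) <- eta[j]"
  else
    "y[j] ~ dnorm(eta[j], tau_res)"
  # non-centered random intercept (b = sd_b * u): mixes far better for
  # the weakly identified intercept SD of a binary-outcome mixed model
  code <- sprintf("model {
  for (j in 1:N) {
    %s
    eta[j] <- inprod(beta[1:P], X[j, 1:P]) + sd_b * u[subj[j]]%s
  }
  for (i in 1:S) { u[i] ~ dnorm(0, 1) }
  for (kk in 1:P) { beta[kk] ~ dnorm(0, beta_prec) }
  sd_b ~ dnorm(0, ri_prec) T(0,)
", lhs, paste(inc_terms, collapse = ""))
  if (spec$outcome == "bmi")
    code <- paste0(code,
      "  sd_res ~ dnorm(0, res_prec) T(0,)\n  tau_res <- pow(sd_res, -2)\n")
  for (e in pd$incomplete) {
    nm <- e$name
    code <- paste0(code, switch(e$family,
      normal = sprintf("
  for (i in 1:S) { v_%s[i] ~ dnorm(inprod(a_%s[1:Q], W[i, 1:Q]), tau_%s) }
  for (q in 1:Q) { a_%s[q] ~ dnorm(0, 0.01) }
  sd_%s ~ dnorm(0, 0.04) T(0,)
  tau_%s <- pow(sd_%s, -2)
  b_%s ~ dnorm(0, beta_prec)
", nm, nm, nm, nm, nm, nm, nm, nm),
      logistic = sprintf("
  for (i in 1:S) {
    v_%s[i] ~ dbern(pi_%s[i])
    logit(pi_%s[i]) <- inprod(a_%s[1:Q], W[i, 1:Q])
  }
  for (q in 1:Q) { a_%s[q] ~ dnorm(0, 0.01) }
  b_%s ~ dnorm(0, beta_prec)
", nm, nm, nm, nm, nm, nm),
      cumlogit = {
        # cutpoints absorb the intercept; the regression part uses the
        # non-intercept predictor columns only (none when Q == 1)
        has_reg <- ncol(pd$W) > 1
        lin <- if (has_reg) "inprod(a_NM[1:Qm], W[i, 2:Q])" else "0"
        reg <- if (has_reg)
          "\n  for (q in 1:Qm) { a_NM[q] ~ dnorm(0, 0.01) }" else ""
        tmpl <- paste0("
  for (i in 1:S) {
    v_NM[i] ~ dcat(pi_NM[i, 1:3])
    logit(q1_NM[i]) <- c_NM[1] - ", lin, "
    logit(q2_NM[i]) <- c_NM[2] - ", lin, "
    pi_NM[i, 1] <- q1_NM[i]
    pi_NM[i, 2] <- q2_NM[i] - q1_NM[i]
    pi_NM[i, 3] <- 1 - q2_NM[i]
  }", reg, "
  c_NM[1] ~ dnorm(0, 0.01)
  d_NM ~ dnorm(0, 0.01) T(0,)
  c_NM[2] <- c_NM[1] + d_NM
  b_NM2 ~ dnorm(0, beta_prec)
  b_NM3 ~ dnorm(0, beta_prec)
")
        gsub("NM", nm, tmpl, fixed = TRUE)
      }))
  }
  paste0(code, "}\n")
}

run_jags <- function(spec, pd) {
  jdata <- list(y = pd$y, X = pd$X, N = nrow(pd$X), P = ncol(pd$X),
                S = pd$S, subj = pd$subj,
                beta_prec = 1 / spec$prior_beta_sd^2,
                ri_prec = 1 / spec$prior_ri_scale^2)
  if (spec$outcome == "bmi") jdata$res_prec <- 1 / spec$prior_resid_scale^2
  if (length(pd$incomplete)) {
    jdata$W <- pd$W
    jdata$Q <- ncol(pd$W)
    if (any(vapply(pd$incomplete, function(e) e$family == "cumlogit", TRUE)) &&
        ncol(pd$W) > 1)
      jdata$Qm <- ncol(pd$W) - 1L
    for (e in pd$incomplete) jdata[[paste0("v_", e$name)]] <- e$values
  }
  monitors <- c("beta", "sd_b",
                if (spec$outcome == "bmi") "sd_res",
                unlist(lapply(pd$incomplete, function(e)
                  c(paste0("v_", e$name),
                    if (e$family == "cumlogit") paste0("b_", e$name, c(2, 3))
                    else paste0("b_", e$name)))))
  code <- build_jags_code(spec, pd)
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(spec$n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + ch))
  jm <- rjags::jags.model(textConnection(code), data = jdata, inits = inits,
                          n.chains = spec$n_chains, n.adapt = spec$n_adapt,
                          quiet = TRUE)
  update(jm, spec$n_burn, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = spec$n_iter, thin = spec$thin,
                      progress.bar = "none")
}

assemble_fit <- function(samples, spec, pd, data) {
  vn <- coda::varnames(samples)
  beta_idx <- grep("^beta\\[", vn)
  coef_names <- pd$terms
  # coefficient chains on the original covariate scale
  chains <- lapply(samples, function(ch) {
    M <- as.matrix(ch)
    B <- M[, beta_idx, drop = FALSE]
    colnames(B) <- coef_names
    B <- sweep(B, 2L, pd$scales * pd$y_sd, `*`)
    B[, "(Intercept)"] <- B[, "(Intercept)"] + pd$y_mean
    extra <- M[, "sd_b", drop = FALSE] * pd$y_sd
    if ("sd_res" %in% vn) extra <- cbind(extra, M[, "sd_res"] * pd$y_sd)
    for (e in pd$incomplete) {
      if (e$family == "cumlogit") {
        for (s in 2:3)
          extra <- cbind(extra, M[, paste0("b_", e$name, s)] * pd$y_sd)
      } else {
        extra <- cbind(extra, M[, paste0("b_", e$name)] * e$scales * pd$y_sd)
      }
    }
    inc_terms <- unlist(lapply(pd$incomplete, function(e) e$terms))
    colnames(extra) <- c("sd_random_intercept",
                         if ("sd_res" %in% vn) "sd_residual", inc_terms)
    coda::mcmc(cbind(B, extra), start = start(ch), thin = coda::thin(ch))
  })
  chains <- coda::as.mcmc.list(chains)

  missing_draws <- lapply(pd$incomplete, function(e) {
    cols <- paste0("v_", e$name, "[", seq_len(pd$S), "]")
    draws <- do.call(rbind, lapply(samples, function(ch) as.matrix(ch)[, cols,
                                                                       drop = FALSE]))
    list(info = e, draws = draws)
  })

  all_draws <- do.call(rbind, lapply(chains, as.matrix))
  nms <- colnames(all_draws)
  est <- colMeans(all_draws)
  ql <- apply(all_draws, 2L, quantile, 0.025)
  qu <- apply(all_draws, 2L, quantile, 0.975)
  tp <- apply(all_draws, 2L, function(d) {
    p <- 2 * min(mean(d > 0), mean(d < 0))
    min(max(p, 1 / length(d)), 1)
  })
  ess <- tryCatch(coda::effectiveSize(chains), error = function(e) rep(NA, length(nms)))
  rhat <- if (length(chains) >= 2)
    tryCatch(coda::gelman.diag(chains, autoburnin = FALSE,
                               multivariate = FALSE)$psrf[, 1],
             error = function(e) rep(NA_real_, length(nms)))
  else rep(NA_real_, length(nms))
  logistic <- spec$outcome == "nafld"
  sd_terms <- nms %in% c("sd_random_intercept", "sd_residual")
  summ <- data.frame(
    term = nms,
    estimate = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(est), est),
    ci_lower = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(ql), ql),
    ci_upper = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(qu), qu),
    tail_prob = tp, ess = as.numeric(ess), rhat = as.numeric(rhat),
    row.names = NULL)
  summ$scale <- ifelse(sd_terms, "sd",
                       ifelse(logistic, "odds_ratio", "linear"))
  fixed <- !sd_terms
  converged <- all(is.na(summ$rhat[fixed])) || all(summ$rhat[fixed] < 1.1,
                                                   na.rm = TRUE)
  structure(list(summary = summ, samples = chains,
                 missing_draws = missing_draws, spec = spec,
                 data = pd$data, prepared = pd, converged = converged),
            class = "diet_model_fit")
}

#' Bayesian random-intercept logistic model of NAFLD on dietary exposures
#'
#' Fits, by MCMC in JAGS, a logistic mixed model of steatosis on dietary
#' exposure scores and covariates with a mean-zero participant random
#' intercept. Missing values in covariates are imputed simultaneously
#' with the regression coefficients through the conditional models of the
#' [imputation_spec()] (joint-modelling imputation), so
#' coefficient uncertainty automatically reflects the missing data.
#' Covariates are standardized internally for sampling and all reported
#' coefficients are back-transformed to the original units (odds ratios
#' per unit: per kcal for energy, per year for time, and so on; the
#' intercept refers to centred covariates).
#'
#' @param data Participant-visit data frame (`id`, outcome, exposure and
#'   covariate columns; covariates named as in [model_spec()]).
#' @param spec A [model_spec()] with `outcome = "nafld"`.
#' @param imputation An [imputation_spec()].
#' @param strict Error (rather than flag) when the Gelman-Rubin
#'   diagnostic exceeds 1.1 for a fixed effect.
#' @return Object of class `diet_model_fit`: `summary` (posterior mean as
#'   odds ratio, 95% credible interval, tail probability, effective
#'   sample size, Rhat), `samples` (coda::mcmc.list of coefficients on
#'   the log-odds scale in original units), `missing_draws` (retained
#'   posterior draws of every incomplete covariate), `converged`.
#' @export
fit_logistic_mixed <- function(data, spec, imputation = imputation_spec(),
                               strict = FALSE) {
  if (spec$outcome != "nafld") stop("spec$outcome must be 'nafld'")
  pd <- prepare_model_data(data, spec, imputation)
  samples <- run_jags(spec, pd)
  fit <- assemble_fit(samples, spec, pd, data)
  if (strict && !fit$converged)
    stop("MCMC did not converge (max Rhat ",
         round(max(fit$summary$rhat, na.rm = TRUE), 3), ")")
  fit
}

#' Bayesian linear mixed model of BMI on dietary exposures
#'
#' The Gaussian-outcome counterpart of [fit_logistic_mixed()], used to
#' probe BMI as a mediating factor: continuous BMI is regressed on the
#' dietary exposures, the model-2 confounders (minus BMI itself), a
#' participant random intercept and, conventionally, a diet-by-time
#' interaction, with the same simultaneous covariate imputation.
#'
#' @inheritParams fit_logistic_mixed
#' @param spec A [model_spec()] with `outcome = "bmi"` (add
#'   `interactions = "diet_time"` for the mediator analysis).
#' @return A `diet_model_fit`; coefficients are on the linear BMI scale
#'   (kg/m^2 per unit of predictor).
#' @export
fit_bmi_lmm <- function(data, spec, imputation = imputation_spec(),
                        strict = FALSE) {
  if (spec$outcome != "bmi") stop("spec$outcome must be 'bmi'")
  pd <- prepare_model_data(data, spec, imputation)
  samples <- run_jags(spec, pd)
  fit <- assemble_fit(samples, spec, pd, data)
  if (strict && !fit$converged) stop("MCMC did not converge")
  fit
}

#' @export
print.diet_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian %s mixed model (%d chains x %d iterations)%s\n",
              ifelse(x$spec$outcome == "nafld", "logistic", "linear"),
              x$spec$n_chains, x$spec$n_iter,
              ifelse(x$converged, "", "  [NOT CONVERGED]")))
  s <- x$summary
  s[, c("estimate", "ci_lower", "ci_upper", "tail_prob")] <-
    round(s[, c("estimate", "ci_lower", "ci_upper", "tail_prob")], digits)
  print(s[, c("term", "estimate", "ci_lower", "ci_upper", "tail_prob",
              "scale")], row.names = FALSE)
  invisible(x)
}

#' Extract completed datasets from a fitted model
#'
#' Takes `m` equally spaced post-burn-in draws of the missing-covariate
#' block from the retained chains and merges each into the observed data,
#' yielding `m` completed datasets (the standard route to refit a
#' smaller covariate set on imputations from the richest model). With no
#' missing data this returns `m` identical copies of the input.
#'
#' @param fit A `diet_model_fit`.
#' @param m Number of completed datasets (must not exceed the number of
#'   retained draws).
#' @return List of `m` data frames.
#' @export
extract_imputations <- function(fit, m = 10) {
  if (!length(fit$missing_draws)) {
    n_draws <- fit$spec$n_chains * fit$spec$n_iter %/% fit$spec$thin
    if (m > n_draws) stop("m exceeds the number of retained draws")
    return(replicate(m, fit$data, simplify = FALSE))
  }
  n_draws <- nrow(fit$missing_draws[[1]]$draws)
  if (m > n_draws) stop("m exceeds the number of retained draws")
  idx <- round(seq(1, n_draws, length.out = m))
  subj <- fit$prepared$subj
  lapply(idx, function(d) {
    out <- fit$data
    for (md in fit$missing_draws) {
      e <- md$info
      vals <- md$draws[d, ]
      filled <- switch(e$family,
                       normal = vals * e$sd + e$mean,
                       logistic = vals,
                       cumlogit = e$levels[vals])
      if (is.integer(out[[e$name]])) filled <- as.integer(round(filled))
      na_rows <- which(is.na(out[[e$name]]))
      out[[e$name]][na_rows] <- filled[subj[na_rows]]
    }
    out
  })
}

#' Pool fitted models as an equal-weight posterior mixture
#'
#' Combines the retained chains of several structurally identical fits
#' (e.g. the refits on `m` completed datasets) into one mixture posterior
#' and summarizes coefficients on the mixture — exact for posterior
#' means, intervals and tail probabilities, with no normality assumption.
#' Effective sample size and Rhat are not defined for a mixture of
#' posteriors from different datasets and are reported as `NA`.
#'
#' @param fits List of `diet_model_fit` objects with identical terms.
#' @return A `diet_model_fit`-like object with the pooled summary and a
#'   single concatenated chain.
#' @export
pool_fits <- function(fits) {
  if (!length(fits)) stop("no fits to pool")
  terms0 <- fits[[1]]$summary$term
  for (f in fits)
    if (!identical(f$summary$term, terms0))
      stop("fits have different model structure")
  draws <- do.call(rbind, lapply(fits, function(f)
    do.call(rbind, lapply(f$samples, as.matrix))))
  logistic <- fits[[1]]$spec$outcome == "nafld"
  nms <- colnames(draws)
  sd_terms <- nms %in% c("sd_random_intercept", "sd_residual")
  est <- colMeans(draws)
  ql <- apply(draws, 2L, quantile, 0.025)
  qu <- apply(draws, 2L, quantile, 0.975)
  tp <- apply(draws, 2L, function(d) {
    p <- 2 * min(mean(d > 0), mean(d < 0)); min(max(p, 1 / length(d)), 1)
  })
  summ <- data.frame(
    term = nms,
    estimate = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(est), est),
    ci_lower = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(ql), ql),
    ci_upper = ifelse(rep(logistic, length(nms)) & !sd_terms, exp(qu), qu),
    tail_prob = tp, ess = NA_real_, rhat = NA_real_, row.names = NULL)
  summ$scale <- ifelse(sd_terms, "sd", ifelse(logistic, "odds_ratio", "linear"))
  structure(list(summary = summ,
                 samples = coda::as.mcmc.list(list(coda::mcmc(draws))),
                 missing_draws = list(), spec = fits[[1]]$spec,
                 data = fits[[1]]$data, prepared = fits[[1]]$prepared,
                 converged = all(vapply(fits, function(f) f$converged, TRUE)),
                 pooled_from = length(fits)),
            class = "diet_model_fit")
}

#' Screen interaction terms and refit without them
#'
#' Fits the model with the requested interactions, judges each
#' interaction "relevant" when its posterior tail probability falls below
#' `tail_threshold` (equivalently, its credible interval at the matching
#' level excludes the null), then refits the model without interaction
#' terms, reusing the imputation draws of the original model: with
#' missing data the refit runs on `m` completed datasets extracted from
#' the interaction model and is pooled; with complete data a single
#' direct refit is returned.
#'
#' @param data Participant-visit data frame.
#' @param spec A [model_spec()] including interaction terms.
#' @param imputation An [imputation_spec()].
#' @param tail_threshold Relevance threshold on the tail probability.
#' @param m Completed datasets for the refit under missing data.
#' @return List with `verdicts` (data frame per interaction term),
#'   `fit_full` (with interactions) and `fit` (the interaction-free
#'   refit).
#' @export
screen_interactions <- function(data, spec, imputation = imputation_spec(),
                                tail_threshold = 0.05, m = 10) {
  if (!length(spec$interactions)) stop("spec contains no interactions")
  fit_full <- if (spec$outcome == "nafld")
    fit_logistic_mixed(data, spec, imputation)
  else fit_bmi_lmm(data, spec, imputation)
  ia_terms <- grep(":", fit_full$summary$term, value = TRUE)
  v <- fit_full$summary[fit_full$summary$term %in% ia_terms, ]
  verdicts <- data.frame(term = v$term, estimate = v$estimate,
                         ci_lower = v$ci_lower, ci_upper = v$ci_upper,
                         tail_prob = v$tail_prob,
                         relevant = v$tail_prob < tail_threshold,
                         row.names = NULL)
  spec0 <- spec
  spec0$interactions <- character()
  refit1 <- function(d) {
    if (spec$outcome == "nafld") fit_logistic_mixed(d, spec0, imputation)
    else fit_bmi_lmm(d, spec0, imputation)
  }
  fit <- if (length(fit_full$missing_draws)) {
    pool_fits(lapply(extract_imputations(fit_full, m), refit1))
  } else refit1(data)
  list(verdicts = verdicts, fit_full = fit_full, fit = fit)
}

#' Univariable energy-adjusted food-group screen
#'
#' Cross-sectional supplement analysis: for every food group at baseline,
#' the intake is energy-adjusted by the residual method, standardized to
#' unit SD, and entered alone in an ordinary logistic regression of
#' steatosis, giving an odds ratio per SD of energy-adjusted intake with
#' a Wald 95% confidence interval. Degenerate (constant) groups are
#' flagged and skipped.
#'
#' @param baseline Baseline-visit data frame with `fg_*` columns,
#'   `energy` and `steatosis`.
#' @param groups Food groups to screen.
#' @return Data frame: `group`, `or_per_sd`, `ci_lower`, `ci_upper`,
#'   `p_value`, `skipped`.
#' @export
univariable_foodgroup_screen <- function(baseline, groups = food_groups()) {
  if ("visit" %in% names(baseline))
    baseline <- baseline[baseline$visit == min(baseline$visit), ]
  out <- data.frame(group = groups, or_per_sd = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, skipped = FALSE)
  for (i in seq_along(groups)) {
    x <- baseline[[paste0("fg_", groups[i])]]
    if (is.null(x)) stop("missing column: fg_", groups[i])
    if (sd(x, na.rm = TRUE) == 0) { out$skipped[i] <- TRUE; next }
    adj <- energy_residual(x, baseline$energy)
    z <- adj / sd(adj, na.rm = TRUE)
    fit <- glm(baseline$steatosis ~ z, family = binomial())
    cf <- summary(fit)$coefficients["z", ]
    out$or_per_sd[i] <- exp(cf["Estimate"])
    out$ci_lower[i] <- exp(cf["Estimate"] - 1.96 * cf["Std. Error"])
    out$ci_upper[i] <- exp(cf["Estimate"] + 1.96 * cf["Std. Error"])
    out$p_value[i] <- cf["Pr(>|z|)"]
  }
  out
}
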