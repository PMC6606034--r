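# Logistic models of claim replication: univariate, multivariate and
# interaction families, min-max rescaled predictors, Wald odds-ratio CIs,
# Benjamini-Hochberg correction and predicted-probability surfaces.

#' Min-max rescale a predictor to [0, 1]
#'
#' `(x - min(x)) / (max(x) - min(x))` over the analysis subsample, making
#' odds ratios comparable across predictors. A constant column cannot be
#' rescaled and raises a degenerate-predictor error.
#'
#' @param x numeric vector.
#' @return vector in `[0, 1]`.
#' @export
#' @examples
#' rescale_minmax(c(1, 2, 3)) # 0 0.5 1
rescale_minmax <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  r <- range(x)
  if (r[1] == r[2]) {
    stop("degenerate predictor: constant column cannot be min-max rescaled",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

replication_predictors <- c("L_supt", "S_ind", "M_ind", "K_ind", "C", "J", "CV")

#' Assemble the per-claim model input table
#'
#' Joins the replication indicator with the seven predictors — literature
#' support `L_supt`, social/methodological/knowledge independence
#' `S_ind`/`M_ind`/`K_ind`, centralization `C`, journal prominence `J`
#' (mean journal score of the claim's papers) and experimental variability
#' `CV` — and min-max rescales each predictor over the analysis subsample.
#'
#' @param evaluation per-claim data frame carrying `claim_id, R` and the
#'   seven raw predictor columns.
#' @return data frame with `R` and the rescaled predictors; raw columns kept
#'   with a `.raw` suffix.
#' @export
model_input <- function(evaluation) {
  need <- c("claim_id", "R", replication_predictors)
  missing <- setdiff(need, names(evaluation))
  if (length(missing)) {
    stop("model_input: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- evaluation[, need, drop = FALSE]
  for (p in replication_predictors) {
    out[[paste0(p, ".raw")]] <- out[[p]]
    out[[p]] <- rescale_minmax(out[[p]])
  }
  out
}

#' Fit a replication logistic model
#'
#' Three model families predicting the replication indicator `R`:
#' * `"univariate"` — `R ~ predictor` for one predictor;
#' * `"multivariate"` — `R ~ L_supt + S_ind + M_ind + K_ind + C + J + CV`;
#' * `"interaction"` — `R ~ L_supt:x + CV` where `x` is `S_ind` or `C`
#'   (product term plus variability adjustment, no main effects;
#'   `main_effects = TRUE` adds them).
#'
#' Fitting is maximum likelihood via [stats::glm()] with the logit link.
#' Odds-ratio CIs are Wald intervals (`exp(beta +/- 1.96 SE)`). Perfect
#' separation is detected (non-converged fit or exploding coefficients) and
#' flagged; a singular design aborts with the aliased columns named.
#'
#' @param data model input from [model_input()] (rescaled predictors).
#' @param family_tag `"univariate"`, `"multivariate"` or `"interaction"`.
#' @param predictor the single predictor (univariate family).
#' @param interaction_with `"S_ind"` or `"C"` (interaction family).
#' @param main_effects include main effects in the interaction family.
#' @param conf_level Wald CI coverage.
#' @return a `replication_fit`: list with `fit` (the glm), `table` (term,
#'   estimate, se, or, or_lo, or_hi, p), `family_tag`, `separation` flag.
#' @export
fit_logistic <- function(data, family_tag = c("univariate", "multivariate",
                                              "interaction"),
                         predictor = NULL, interaction_with = c("S_ind", "C"),
                         main_effects = FALSE, conf_level = 0.95) {
  family_tag <- match.arg(family_tag)
  if (length(unique(data$R)) < 2L) {
    stop("fit_logistic: outcome has a single class", call. = FALSE)
  }
  fml <- switch(family_tag,
    univariate = {
      stopifnot(!is.null(predictor), predictor %in% names(data))
      stats::reformulate(predictor, response = "R")
    },
    multivariate = stats::reformulate(replication_predictors, response = "R"),
    interaction = {
      interaction_with <- match.arg(interaction_with)
      term <- paste0("L_supt:", interaction_with)
      rhs <- if (main_effects) {
        c("L_supt", interaction_with, term, "CV")
      } else {
        c(term, "CV")
      }
      stats::as.formula(paste("R ~", paste(rhs, collapse = " + ")))
    })
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("fit_logistic: singular design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  separation <- !fit$converged || any(abs(cf) > 15)
  if (separation) {
    warning("fit_logistic: possible perfect separation; ",
            "coefficients are unreliable (consider penalized fits)",
            call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
                    or = exp(unname(cf)),
                    or_lo = exp(unname(cf) - zq * unname(se)),
                    or_hi = exp(unname(cf) + zq * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(cf) / unname(se))),
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, family_tag = family_tag,
                 separation = separation),
            class = "replication_fit")
}

#' @export
print.replication_fit <- function(x, ...) {
  cat("replication_fit (", x$family_tag, ")\n", sep = "")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Univariate odds-ratio panel
#'
#' Fits one univariate logistic model per predictor and collects
#' non-intercept odds ratios with BH-adjusted p-values — the standard
#' predictor-panel layout.
#'
#' @param data model input from [model_input()].
#' @param predictors predictor names (default all seven).
#' @return data frame `term, estimate, se, or, or_lo, or_hi, p, p_adj`.
#' @export
univariate_panel <- function(data, predictors = replication_predictors) {
  rows <- lapply(predictors, function(p) {
    tab <- fit_logistic(data, "univariate", predictor = p)$table
    tab[tab$term != "(Intercept)", , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validated front-end to
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Predicted-probability surface of an interaction model
#'
#' Evaluates the fitted replication probability over a grid of the two
#' interacting predictors at a fixed variability `CV`, for contour plots of
#' how replication probability grows with support and
#' decentralization/independence.
#'
#' @param fit a `replication_fit` of the interaction family.
#' @param n_grid grid resolution per axis (default 26).
#' @param cv fixed CV value (default 0, i.e. the subsample minimum after
#'   rescaling).
#' @return data frame `L_supt, x, prob` where `x` is the interacting
#'   predictor; its name is stored in attribute `"with"`.
#' @export
predict_surface <- function(fit, n_grid = 26, cv = 0) {
  stopifnot(inherits(fit, "replication_fit"))
  if (fit$family_tag != "interaction") {
    stop("predict_surface: requires a fitted interaction model", call. = FALSE)
  }
  vars <- all.vars(stats::formula(fit$fit))
  with_var <- setdiff(vars, c("R", "L_supt", "CV"))
  g <- seq(0, 1, length.out = n_grid)
  grid <- expand.grid(L_supt = g, x = g)
  nd <- data.frame(L_supt = grid$L_supt, CV = cv)
  nd[[with_var]] <- grid$x
  grid$prob <- predict(fit$fit, newdata = nd, type = "response")
  attr(grid, "with") <- with_var
  grid
}
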