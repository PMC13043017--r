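#' Crossed random-intercept linear mixed model for version effects
#'
#' Fits `value ~ version + (1 | doc_id) + (1 | rater_id)` by REML: document
#' version as the fixed effect of interest and crossed random intercepts for
#' document and rater, the standard model when every rater scores every
#' document version. Inference on the fixed effects is Wald-z (normal
#' approximation): `p = 2 * pnorm(-|beta/se|)` and 95% CI `beta ± 1.96 se`.
#' All pairwise version contrasts are reported from a single fit by linear
#' combination of the coefficients, so they are exactly consistent under a
#' change of reference level. Mixed-model p-values are reported unadjusted.
#'
#' @param data Long tibble with columns `rater_id`, `doc_id`, `version` and
#'   the outcome.
#' @param outcome Name of the outcome column (default `"value"`).
#' @param reference Reference version level (default `"original"` if present,
#'   else the first observed level).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `icf_lmm`: list with `contrasts` (tibble:
#'   `outcome`, `contrast`, `beta`, `se`, `ci_low`, `ci_high`, `z`, `p`),
#'   `varcomp` (named vector: `doc`, `rater`, `residual` variances),
#'   `singular`, `converged`, `logLik`, `reference` and the underlying
#'   `lme4` fit in `$model`.
#' @export
fit_lmm <- function(data, outcome = "value", reference = NULL,
                    conf_level = 0.95) {
  assert_columns(data, c("rater_id", "doc_id", "version", outcome), "LMM input")
  versions <- unique(as.character(data$version))
  if (length(versions) < 2) abort_validation("need at least 2 versions")
  if (length(unique(data$doc_id)) < 2 || length(unique(data$rater_id)) < 2) {
    abort_validation("need at least 2 documents and 2 raters for crossed random intercepts")
  }
  reference <- reference %||% (if ("original" %in% versions) "original" else versions[1])
  if (!reference %in% versions) {
    abort_validation(sprintf("reference level '%s' not present in data", reference))
  }

  df <- data.frame(
    value = as.numeric(data[[outcome]]),
    version = stats::relevel(factor(as.character(data$version)), ref = reference),
    doc_id = factor(data$doc_id),
    rater_id = factor(data$rater_id)
  )
  quiet_lmer <- function(optimizer = NULL) {
    ctrl <- if (is.null(optimizer)) {
      lme4::lmerControl(check.conv.singular = "ignore")
    } else {
      lme4::lmerControl(check.conv.singular = "ignore", optimizer = optimizer)
    }
    withCallingHandlers(
      lme4::lmer(value ~ version + (1 | doc_id) + (1 | rater_id),
                 data = df, REML = TRUE, control = ctrl),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  has_conv_failure <- function(fit) {
    msgs <- fit@optinfo$conv$lme4$messages
    !is.null(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE))
  }
  fit <- quiet_lmer()
  if (has_conv_failure(fit)) fit <- quiet_lmer("bobyqa") # retry before giving up
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- !has_conv_failure(fit)
  if (!converged) {
    rlang::abort(
      paste0("mixed model failed to converge:\n",
             paste(conv_msgs, collapse = "\n")),
      class = c("icfeval_convergence_error", "icfeval_error")
    )
  }
  singular <- lme4::isSingular(fit)

  # coefficient vector over all version levels (reference pinned at 0)
  levs <- levels(df$version)
  coefs <- lme4::fixef(fit)
  vc_fixed <- as.matrix(stats::vcov(fit))
  beta_of <- stats::setNames(numeric(length(levs)), levs)
  idx_of <- stats::setNames(rep(NA_integer_, length(levs)), levs)
  for (l in setdiff(levs, reference)) {
    nm <- paste0("version", l)
    beta_of[l] <- coefs[[nm]]
    idx_of[l] <- which(names(coefs) == nm)
  }

  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[2]; b <- pr[1] # a vs b, later level first to mirror reporting
    beta <- beta_of[[a]] - beta_of[[b]]
    va <- if (is.na(idx_of[[a]])) 0 else vc_fixed[idx_of[[a]], idx_of[[a]]]
    vb <- if (is.na(idx_of[[b]])) 0 else vc_fixed[idx_of[[b]], idx_of[[b]]]
    vab <- if (is.na(idx_of[[a]]) || is.na(idx_of[[b]])) 0 else vc_fixed[idx_of[[a]], idx_of[[b]]]
    se <- sqrt(max(0, va + vb - 2 * vab))
    z <- if (se > 0) beta / se else ifelse(beta == 0, 0, sign(beta) * Inf)
    tibble::tibble(
      outcome = outcome,
      contrast = sprintf("%s vs %s", a, b),
      beta = beta, se = se,
      ci_low = beta - zcrit * se, ci_high = beta + zcrit * se,
      z = z, p = 2 * stats::pnorm(-abs(z))
    )
  })

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(
    doc = vc$vcov[vc$grp == "doc_id"],
    rater = vc$vcov[vc$grp == "rater_id"],
    residual = vc$vcov[vc$grp == "Residual"]
  )

  structure(
    list(
      contrasts = dplyr::bind_rows(rows),
      varcomp = varcomp,
      singular = singular,
      converged = converged,
      logLik = as.numeric(stats::logLik(fit)),
      reference = reference,
      model = fit
    ),
    class = "icf_lmm"
  )
}

#' @export
print.icf_lmm <- function(x, ...) {
  cat(sprintf(
    "<icf_lmm> outcome '%s', reference '%s'%s\n",
    x$contrasts$outcome[1], x$reference,
    if (x$singular) " (singular fit)" else ""
  ))
  print(x$contrasts, ...)
  cat("variance components:\n")
  print(x$varcomp)
  invisible(x)
}
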