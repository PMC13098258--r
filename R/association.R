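#' Centered log-ratio transform of a relative-abundance table
#'
#' Per sample, `y_i = log(x_i / g(x))` with `g` the geometric mean over
#' species, after zero replacement. The default rule replaces every zero
#' by half the smallest nonzero relative abundance in the whole table and
#' re-closes each row. Every output row sums to zero, and the transform
#' is invariant to rescaling a sample's composition by a positive
#' constant.
#'
#' @param x samples x species matrix of non-negative relative abundances.
#' @param pseudocountRule `"half-min"` (default) or `"none"` (zeros must
#'   then be absent).
#' @return samples x species matrix of CLR values.
#' @export
clrTransform <- function(x, pseudocountRule = c("half-min", "none")) {
  pseudocountRule <- match.arg(pseudocountRule)
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  zeroRows <- rowSums(x) == 0
  if (any(zeroRows))
    stop("all-zero sample row(s): ",
         paste(head(rownames(x)[zeroRows], 5), collapse = ", "))
  x <- x / rowSums(x)  # close first so the zero rule is scale-invariant
  if (any(x == 0)) {
    if (pseudocountRule == "none")
      stop("zeros present but pseudocountRule = 'none'")
    mn <- min(x[x > 0])
    x[x == 0] <- 0.5 * mn
    x <- x / rowSums(x)
  }
  lg <- log(x)
  lg - rowMeans(lg)
}

#' Prevalence filter for species
#'
#' Keeps species detected (nonzero abundance) in at least
#' `minPrevalence` of samples (inclusive; default 1%).
#'
#' @param x samples x species abundance matrix.
#' @param minPrevalence fraction of samples, in \[0, 1\].
#' @return character vector of retained species ids.
#' @export
filterSpecies <- function(x, minPrevalence = 0.01) {
  prev <- colMeans(as.matrix(x) > 0)
  colnames(x)[prev >= minPrevalence]
}

#' Case-count filter for diseases
#'
#' Keeps diseases with at least `minCases` cases (inclusive; default
#' 100). Remaining samples act as controls per disease.
#'
#' @param phenotypes data.frame with one 0/1 column per disease.
#' @param diseases candidate disease column names.
#' @param minCases minimum case count.
#' @return character vector of retained disease names.
#' @export
filterDiseases <- function(phenotypes, diseases, minCases = 100) {
  cases <- vapply(diseases, function(d) sum(phenotypes[[d]] == 1),
                  numeric(1))
  diseases[cases >= minCases]
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, `>= 1`.
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (any(m < 1)) stop("m must be >= 1")
  alpha / m
}

# align phenotype rows to a sample id vector, failing fast on mismatch
alignPhenotypes <- function(phenotypes, samples) {
  miss <- setdiff(samples, phenotypes$sample_id)
  if (length(miss))
    stop("samples missing from phenotype table: ",
         paste(head(miss, 5), collapse = ", "))
  phenotypes[match(samples, phenotypes$sample_id), , drop = FALSE]
}

emptyAssoc <- function() {
  data.frame(level = character(), feature_id = character(),
             disease_id = character(), n_cases = integer(),
             n_controls = integer(), effect = numeric(), se = numeric(),
             p_value = numeric(), or = numeric(),
             alpha_corrected = numeric(), significant = logical(),
             note = character())
}

#' Species-level association study (linear layer)
#'
#' Per (species, disease) pair, ordinary least squares of the CLR
#' abundance on the disease indicator adjusted for the covariates
#' (default BMI, sex, age); the reported effect is the disease
#' coefficient with its Wald t-test p-value. Significance is assessed
#' against `alpha / (number of species tested)`. Degenerate designs
#' (constant disease or collinear covariates) yield flagged rows with
#' `NA` p-values rather than silent omissions.
#'
#' @param clr samples x species CLR matrix (rownames = sample ids).
#' @param phenotypes data.frame with `sample_id`, the covariates, and one
#'   0/1 column per disease.
#' @param diseases disease column names to test.
#' @param covariates covariate column names.
#' @param alpha family-wise error rate before correction.
#' @return data.frame with columns `level`, `feature_id`, `disease_id`,
#'   `n_cases`, `n_controls`, `effect`, `se`, `p_value`, `or` (`NA` for
#'   this linear layer), `alpha_corrected`, `significant`, `note`.
#' @export
speciesMwas <- function(clr, phenotypes, diseases,
                        covariates = c("bmi", "sex", "age"), alpha = 0.05) {
  clr <- as.matrix(clr)
  ph <- alignPhenotypes(phenotypes, rownames(clr))
  nSpecies <- ncol(clr)
  alphaC <- bonferroniThreshold(alpha, nSpecies)
  n <- nrow(clr)
  res <- list()
  for (d in diseases) {
    y01 <- ph[[d]]
    nc <- sum(y01 == 1)
    X <- cbind(intercept = 1, disease = y01,
               as.matrix(ph[, covariates, drop = FALSE]))
    degenerate <- length(unique(y01)) < 2L || qr(X)$rank < ncol(X)
    if (degenerate) {
      res[[d]] <- data.frame(
        level = "species", feature_id = colnames(clr), disease_id = d,
        n_cases = nc, n_controls = n - nc, effect = NA_real_,
        se = NA_real_, p_value = NA_real_, or = NA_real_,
        alpha_corrected = alphaC, significant = FALSE,
        note = "degenerate_design")
      next
    }
    fit <- lm.fit(X, clr)
    cf <- fit$coefficients
    if (is.null(dim(cf)))  # single-species input: lm.fit drops to a vector
      cf <- matrix(cf, ncol = 1, dimnames = list(names(cf), colnames(clr)))
    resid <- clr - X %*% cf
    df <- n - ncol(X)
    sigma2 <- colSums(resid^2) / df
    xtxInv <- solve(crossprod(X))
    se <- sqrt(sigma2 * xtxInv[2, 2])
    beta <- cf["disease", ]
    pv <- 2 * pt(-abs(beta / se), df)
    res[[d]] <- data.frame(
      level = "species", feature_id = colnames(clr), disease_id = d,
      n_cases = nc, n_controls = n - nc, effect = unname(beta),
      se = unname(se), p_value = unname(pv), or = NA_real_,
      alpha_corrected = alphaC,
      significant = !is.na(pv) & pv < alphaC, note = "")
  }
  out <- do.call(rbind, c(list(emptyAssoc()), res))
  rownames(out) <- NULL
  out
}

#' Genome-unit presence/absence matrix
#'
#' A unit is present in a sample when at least one MAG of that unit was
#' recovered from it.
#'
#' @param recovery data.frame with `sample_id` and either a `unit_key`
#'   column or `species`/`species_id` plus `unit` columns (a key is then
#'   derived as `<species>_u<unit>`).
#' @param samples full vector of cohort sample ids (so samples without
#'   any MAG yield all-zero rows).
#' @return samples x units binary matrix.
#' @export
unitPresenceMatrix <- function(recovery, samples) {
  if (!"unit_key" %in% names(recovery)) {
    spCol <- if ("species_id" %in% names(recovery)) "species_id" else "species"
    recovery$unit_key <- sprintf("%s_u%s", recovery[[spCol]], recovery$unit)
  }
  units <- sort(unique(recovery$unit_key))
  m <- matrix(0L, nrow = length(samples), ncol = length(units),
              dimnames = list(samples, units))
  keep <- recovery$sample_id %in% samples
  m[cbind(match(recovery$sample_id[keep], samples),
          match(recovery$unit_key[keep], units))] <- 1L
  m
}

#' Within-species association study (logistic layer)
#'
#' Per (genome unit, disease) pair, logistic regression of the disease on
#' unit presence adjusted for the covariates (default sex, age, BMI);
#' reports the odds ratio `exp(beta)` with its Wald p-value. Only units
#' carried by at least `minCarriers` samples are tested; significance is
#' assessed against `alpha / (number of diseases)`. Constant presence
#' columns and fits with fitted probabilities at 0/1 (possible
#' separation) are flagged, never dropped silently.
#'
#' @param presence samples x units binary matrix from
#'   [unitPresenceMatrix()].
#' @param phenotypes data.frame with `sample_id`, covariates, diseases.
#' @param diseases disease column names to test.
#' @param covariates covariate column names.
#' @param minCarriers minimum carrier count per unit (inclusive).
#' @param alpha family-wise error rate before correction.
#' @return data.frame in the same layout as [speciesMwas()], with `or`
#'   filled and `effect` the log odds ratio.
#' @export
withinSpeciesMwas <- function(presence, phenotypes, diseases,
                              covariates = c("sex", "age", "bmi"),
                              minCarriers = 100, alpha = 0.05) {
  presence <- as.matrix(presence)
  ph <- alignPhenotypes(phenotypes, rownames(presence))
  carriers <- colSums(presence == 1)
  units <- colnames(presence)[carriers >= minCarriers]
  alphaC <- bonferroniThreshold(alpha, length(diseases))
  n <- nrow(presence)
  res <- list()
  for (u in units) {
    pres <- presence[, u]
    for (d in diseases) {
      y <- ph[[d]]
      nc <- sum(y == 1)
      row <- data.frame(
        level = "unit", feature_id = u, disease_id = d, n_cases = nc,
        n_controls = n - nc, effect = NA_real_, se = NA_real_,
        p_value = NA_real_, or = NA_real_, alpha_corrected = alphaC,
        significant = FALSE, note = "")
      if (length(unique(pres)) < 2L || length(unique(y)) < 2L) {
        row$note <- "degenerate_design"
      } else {
        dat <- data.frame(y = y, presence = pres,
                          ph[, covariates, drop = FALSE])
        sep <- FALSE
        fit <- withCallingHandlers(
          glm(y ~ ., data = dat, family = binomial()),
          warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
              sep <<- TRUE
            invokeRestart("muffleWarning")
          })
        # glm can separate silently; use its own 0/1 fitted-prob criterion
        if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
          sep <- TRUE
        sm <- summary(fit)$coefficients
        row$effect <- sm["presence", "Estimate"]
        row$se <- sm["presence", "Std. Error"]
        row$p_value <- sm["presence", "Pr(>|z|)"]
        row$or <- exp(row$effect)
        row$significant <- !is.na(row$p_value) && row$p_value < alphaC
        if (sep) row$note <- "possible_separation"
        else if (!fit$converged) row$note <- "not_converged"
      }
      res[[paste(u, d)]] <- row
    }
  }
  out <- do.call(rbind, c(list(emptyAssoc()), res))
  rownames(out) <- NULL
  out
}

#' Novel-species accumulation curve
#'
#' Mean cumulative count of distinct novel species over random sample
#' orderings, with a least-squares line through the mean curve. The slope
#' is expressed per 500 samples, echoing discovery-rate summaries of
#' cohort assembly efforts.
#'
#' @param recovery data.frame with `sample_id`, a species column
#'   (`species_id` or `species`), and a logical `novel` flag.
#' @param nPermutations number of random sample orderings (`>= 1`).
#' @param seed optional integer seed.
#' @return list: `curve` (mean cumulative novel-species count by number
#'   of samples), `slopePer500`, `r2` (`NA` when the curve is constant).
#' @export
accumulationCurve <- function(recovery, nPermutations = 50, seed = NULL) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  spCol <- if ("species_id" %in% names(recovery)) "species_id" else "species"
  samples <- sort(unique(recovery$sample_id))
  novelSets <- lapply(samples, function(s)
    unique(recovery[[spCol]][recovery$sample_id == s & recovery$novel]))
  names(novelSets) <- samples
  nS <- length(samples)
  acc <- matrix(0, nrow = nPermutations, ncol = nS)
  for (p in seq_len(nPermutations)) {
    ord <- sample(samples)
    seen <- character(); cum <- integer(nS)
    for (i in seq_len(nS)) {
      seen <- union(seen, novelSets[[ord[i]]])
      cum[i] <- length(seen)
    }
    acc[p, ] <- cum
  }
  curve <- colMeans(acc)
  idx <- seq_len(nS)
  if (all(curve == curve[1])) {
    return(list(curve = curve, slopePer500 = 0, r2 = NA_real_))
  }
  fit <- lm(curve ~ idx)
  r2 <- 1 - sum(fit$residuals^2) / sum((curve - mean(curve))^2)
  list(curve = curve,
       slopePer500 = unname(coef(fit)["idx"]) * 500,
       r2 = r2)
}
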