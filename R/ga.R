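#' Genetic-algorithm configuration
#'
#' Defaults mirror common real-valued GA settings: population 100, 300
#' generations, crossover probability 0.8, per-gene mutation probability 0.1,
#' 5 elites.
#'
#' @param popSize population size.
#' @param generations number of generations.
#' @param pcrossover probability a selected pair is recombined.
#' @param pmutation per-gene Gaussian mutation probability.
#' @param elitism number of best chromosomes copied unchanged each generation.
#' @param seed integer RNG seed.
#' @return A [GAConfig-class] object.
#' @export
gaConfig <- function(popSize = 100, generations = 300, pcrossover = 0.8,
                     pmutation = 0.1, elitism = 5, seed = 1) {
  new("GAConfig",
    popSize = popSize, generations = generations, pcrossover = pcrossover,
    pmutation = pmutation, elitism = elitism, seed = seed
  )
}

## run fn with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Real-valued genetic algorithm
#'
#' Global minimization over a box by a real-coded GA: binary-tournament
#' selection, blend (BLX-alpha, alpha = 0.5) crossover, bounded Gaussian
#' mutation (SD = 10% of each parameter range) and elitism. Fully reproducible
#' under a fixed seed; non-convergence shows in the trace rather than raising.
#'
#' @param objective function mapping a numeric vector to a scalar to minimize;
#'   must return a finite value (use a large penalty for invalid regions).
#' @param lower,upper finite bounds, equal length.
#' @param config a [GAConfig-class].
#' @param names optional parameter names for the result.
#' @return A [PSMSRFit-class] with the best chromosome (\code{par}), its
#'   objective value and the per-generation elitist best-so-far trace.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- gaOptimize(sphere, rep(-5, 3), rep(5, 3),
#'                   gaConfig(popSize = 40, generations = 60, seed = 7))
#' fit@value
#' @export
gaOptimize <- function(objective, lower, upper, config = gaConfig(),
                       names = NULL) {
  stopifnot(is(config, "GAConfig"), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)), all(upper > lower))
  validObject(config)
  d <- length(lower)
  rng <- upper - lower
  if (is.null(names)) names <- paste0("p", seq_len(d))

  .with_seed(config@seed, function() {
    n <- config@popSize
    pop <- matrix(stats::runif(n * d), n, d)
    pop <- sweep(sweep(pop, 2, rng, "*"), 2, lower, "+")
    fit <- apply(pop, 1, objective)
    bestTrace <- numeric(config@generations)

    for (gen in seq_len(config@generations)) {
      ord <- order(fit)
      nElite <- max(1L, round(config@elitism)) # >= 1 keeps the trace monotone
      elite <- pop[ord[seq_len(nElite)], , drop = FALSE]
      eliteFit <- fit[ord[seq_len(nElite)]]

      ## binary tournament
      nOff <- n - nElite
      i1 <- sample.int(n, nOff, replace = TRUE)
      i2 <- sample.int(n, nOff, replace = TRUE)
      parents <- ifelse(fit[i1] <= fit[i2], i1, i2)
      off <- pop[parents, , drop = FALSE]

      ## BLX-0.5 crossover on consecutive pairs
      for (k in seq_len(floor(nOff / 2))) {
        if (stats::runif(1) < config@pcrossover) {
          aRow <- off[2 * k - 1, ]
          bRow <- off[2 * k, ]
          lo <- pmin(aRow, bRow)
          hi <- pmax(aRow, bRow)
          span <- hi - lo
          cl <- pmax(lo - 0.5 * span, lower)
          cu <- pmin(hi + 0.5 * span, upper)
          off[2 * k - 1, ] <- cl + stats::runif(d) * (cu - cl)
          off[2 * k, ] <- cl + stats::runif(d) * (cu - cl)
        }
      }

      ## bounded Gaussian mutation
      mut <- matrix(stats::runif(nOff * d) < config@pmutation, nOff, d)
      if (any(mut)) {
        noise <- matrix(stats::rnorm(nOff * d, sd = rep(0.1 * rng, each = nOff)),
                        nOff, d)
        off[mut] <- off[mut] + noise[mut]
        off <- pmin(pmax(off, matrix(lower, nOff, d, byrow = TRUE)),
                    matrix(upper, nOff, d, byrow = TRUE))
      }

      offFit <- apply(off, 1, objective)
      pop <- rbind(elite, off)
      fit <- c(eliteFit, offFit)
      bestTrace[gen] <- min(fit)
    }

    bestTrace <- cummin(bestTrace)
    ibest <- which.min(fit)
    par <- pop[ibest, ]
    base::names(par) <- names
    new("PSMSRFit",
      par = par, free = names, value = fit[ibest],
      trace = data.frame(generation = seq_len(config@generations),
                         best = bestTrace),
      ci = matrix(NA_real_, d, 2,
                  dimnames = list(names, c("lower", "upper"))),
      seed = config@seed, condition = "", details = list(config = config)
    )
  })
}

setMethod("show", "PSMSRFit", function(object) {
  cat(sprintf(
    "PSMSRFit%s: NLL = %.6g after %d generations (seed %d)\n",
    if (nzchar(object@condition)) sprintf(" ['%s']", object@condition) else "",
    object@value, nrow(object@trace), as.integer(object@seed)
  ))
  cat("  best parameters:\n")
  print(signif(object@par, 4))
  if (any(is.finite(object@ci))) {
    cat("  95% profile confidence limits:\n")
    print(signif(object@ci[rowSums(is.finite(object@ci)) > 0, , drop = FALSE], 4))
  }
})

#' @describeIn gaOptimize best parameter vector of a fit
#' @param fit a [PSMSRFit-class].
#' @export
bestParams <- function(fit) {
  stopifnot(is(fit, "PSMSRFit"))
  fit@par
}

#' @describeIn gaOptimize best objective value of a fit
#' @export
objectiveValue <- function(fit) {
  stopifnot(is(fit, "PSMSRFit"))
  fit@value
}
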