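#' Equally weighted waveform-averaging ensemble
#'
#' The ensemble prediction is the element-wise mean of the member models'
#' predicted ABP waveforms; SBP/DBP are extracted from the averaged waveform
#' afterwards (not averaged per member).
#'
#' @param members list of trained \code{dcae_model}s (nonempty).
#' @param ppg matrix of raw PPG windows or a \code{window_set}.
#' @return matrix of ensemble-predicted ABP windows in mmHg.
#' @export
ensemble_predict <- function(members, ppg) {
  if (length(members) < 1) stop("empty member set", call. = FALSE)
  preds <- lapply(members, predict, ppg)
  Reduce(`+`, preds) / length(preds)
}

#' Precompute the inputs of the ensemble fitness function
#'
#' Runs every candidate model once on the evaluation windows and stacks the
#' predicted waveforms, so that fitness evaluation during the genetic search
#' never re-runs a model.
#'
#' @param models list of candidate trained models (one per CV model; 20 at
#'   full scale), or a \code{cv_results} object.
#' @param ppg evaluation PPG windows (matrix or \code{window_set}).
#' @param ref_abp matching reference ABP windows (matrix).
#' @return an object of class \code{fitness_input}: list with
#'   \code{pred_stack} (n_windows x len x n_models array), \code{ref_sbp},
#'   \code{ref_dbp}, and \code{model_ids}.
#' @export
fitness_input <- function(models, ppg, ref_abp) {
  if (inherits(models, "cv_results")) {
    ids <- vapply(models, function(r)
      sprintf("%s_fold%d", r$family, r$fold_id), "")
    models <- lapply(models, `[[`, "model")
  } else {
    ids <- if (!is.null(names(models))) names(models)
           else sprintf("model%d", seq_along(models))
  }
  if (inherits(ppg, "window_set")) ppg <- ppg$ppg
  preds <- lapply(models, predict, ppg)
  stack <- array(unlist(preds),
                 dim = c(nrow(ppg), ncol(ref_abp), length(preds)))
  bp <- extract_sbp_dbp(ref_abp)
  structure(list(pred_stack = stack, ref_sbp = bp$sbp, ref_dbp = bp$dbp,
                 model_ids = ids), class = "fitness_input")
}

#' Build a fitness input directly from precomputed prediction tables
#' @param pred_stack n_windows x len x n_models array of predicted ABP
#'   waveforms (mmHg).
#' @param ref_abp n_windows x len matrix of reference waveforms.
#' @param model_ids optional labels.
#' @rdname fitness_input
#' @export
fitness_input_from_predictions <- function(pred_stack, ref_abp,
                                           model_ids = NULL) {
  bp <- extract_sbp_dbp(ref_abp)
  if (is.null(model_ids)) model_ids <- sprintf("model%d",
                                               seq_len(dim(pred_stack)[3]))
  structure(list(pred_stack = pred_stack, ref_sbp = bp$sbp,
                 ref_dbp = bp$dbp, model_ids = model_ids),
            class = "fitness_input")
}

#' Ensemble fitness: mean of the SBP and DBP Pearson correlations
#'
#' Decodes the binary chromosome into an equally weighted ensemble, averages
#' the selected members' waveforms, extracts per-window SBP (max) and DBP
#' (min), and returns \eqn{\frac{1}{2}(r_{SBP} + r_{DBP})} against the
#' reference. The all-zero chromosome decodes to no ensemble and is assigned
#' the worst fitness, -1, rather than repaired.
#'
#' @param bits binary vector (0/1), one bit per candidate model.
#' @param input a \code{fitness_input}.
#' @return fitness in \eqn{[-1, 1]}.
#' @export
ga_fitness <- function(bits, input) {
  sel <- which(bits != 0)
  if (length(sel) == 0) return(-1)
  cpp_ensemble_fitness(input$pred_stack, sel, input$ref_sbp, input$ref_dbp)
}

#' Genetic algorithm configuration
#'
#' Defaults follow the full-scale search: population 32, 2000 generations,
#' single-point crossover, mutation applied to 95% of offspring (one
#' uniformly chosen bit flipped), elitism of 1.
#'
#' @param population_size chromosomes per generation (>= 2).
#' @param generations number of generations; 0 scores only the initial
#'   random population.
#' @param mutation_rate probability that an offspring has one random bit
#'   flipped.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed integer seed.
#' @export
ga_config <- function(population_size = 32, generations = 2000,
                      mutation_rate = 0.95, elitism = 1, seed = 1L) {
  if (population_size < 2)
    stop("invalid config: population_size must be >= 2", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("invalid config: mutation_rate must lie in [0, 1]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Evolve the model-selection chromosome
#'
#' Generational genetic algorithm over binary model-selection vectors:
#' tournament selection (size 2), single-point crossover, per-offspring
#' single-bit mutation, elitism. With elitism >= 1 the best-ever fitness is
#' non-decreasing across generations. Candidate predictions must already be
#' precomputed in \code{input}; fitness evaluation never re-runs a model.
#'
#' @param input a \code{fitness_input}.
#' @param config a [ga_config()].
#' @return list with \code{best_bits}, \code{best_fitness}, \code{trace}
#'   (best-ever fitness per generation) and \code{selected} (indices of the
#'   chosen models).
#' @export
evolve_ga <- function(input, config = ga_config()) {
  nbits <- dim(input$pred_stack)[3]
  withr::with_seed(config$seed, {
    pop <- matrix(sample(0:1, config$population_size * nbits, replace = TRUE),
                  nrow = config$population_size)
    fit <- apply(pop, 1, ga_fitness, input = input)
    best_i <- which.max(fit)
    best_bits <- pop[best_i, ]
    best_fit <- fit[best_i]
    trace <- numeric(config$generations)
    if (config$generations > 0) for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(0L, config$population_size, nbits)
      ne <- min(config$elitism, config$population_size)
      if (ne > 0) newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], ]
      if (ne < config$population_size) for (i in seq.int(ne + 1, config$population_size)) {
        pick <- function() {
          cand <- sample.int(config$population_size, 2)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        cp <- if (nbits > 1) sample.int(nbits - 1, 1) else 1
        child <- c(p1[seq_len(cp)], p2[seq.int(cp + 1, nbits)])
        if (runif(1) < config$mutation_rate) {
          flip <- sample.int(nbits, 1)
          child[flip] <- 1L - child[flip]
        }
        newpop[i, ] <- child
      }
      pop <- newpop
      fit <- apply(pop, 1, ga_fitness, input = input)
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best_bits <- pop[gi, ]
      }
      trace[g] <- best_fit
    }
    list(best_bits = best_bits, best_fitness = best_fit, trace = trace,
         selected = which(best_bits == 1))
  })
}

#' Exhaustive search over all nonempty model subsets
#'
#' Brute-force oracle for [evolve_ga()]: evaluates the fitness of every
#' nonempty subset of candidates and returns the argmax. Practical up to a
#' dozen candidates; refuses beyond 25.
#'
#' @param input a \code{fitness_input}.
#' @return list with \code{best_bits}, \code{best_fitness},
#'   \code{selected}.
#' @export
exhaustive_best <- function(input) {
  m <- dim(input$pred_stack)[3]
  if (m > 25) stop("refusing exhaustive search over more than 25 candidates",
                   call. = FALSE)
  best_fit <- -Inf
  best_bits <- NULL
  for (code in seq_len(2^m - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L))
    f <- ga_fitness(bits, input)
    if (f > best_fit) {
      best_fit <- f
      best_bits <- bits
    }
  }
  list(best_bits = best_bits, best_fitness = best_fit,
       selected = which(best_bits == 1))
}
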