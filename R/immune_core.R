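# Clonal-selection engine shared by the thresholding (AIA) and clustering
# (ICA) optimizers. Antibodies are 0/1 integer vectors; antibody groups are
# matrices with one antibody per row. Each 8-bit block encodes one gray value,
# most-significant bit first.

#' Encode a gray value as an 8-bit antibody block
#'
#' @param value Integer gray level(s) in \[0, 255\].
#' @return A 0/1 integer vector of length `8 * length(value)`, MSB first;
#'   [decode_gray()] inverts it exactly.
#' @examples
#' encode_gray(128)  # 1 0 0 0 0 0 0 0
#' @export
encode_gray <- function(value) {
  if (anyNA(value) || any(value < 0) || any(value > 255) ||
      any(value != as.integer(value))) {
    stop("`value` must be integer gray levels in [0, 255]", call. = FALSE)
  }
  bits <- vapply(as.integer(value),
                 function(v) bitwAnd(bitwShiftR(v, 7:0), 1L),
                 integer(8))
  as.integer(bits)
}

#' Decode 8-bit antibody blocks back to gray values
#'
#' @param bits A 0/1 vector whose length is a positive multiple of 8.
#' @return Integer gray value(s), one per 8-bit block.
#' @export
decode_gray <- function(bits) {
  assert_bits(bits)
  m <- matrix(as.integer(bits), nrow = 8L)
  as.integer(colSums(m * 2L^(7:0)))
}

assert_bits <- function(bits, arg = "bits") {
  n <- length(bits)
  if (n == 0L || n %% 8L != 0L || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be a 0/1 vector with length a positive multiple of 8", arg),
         call. = FALSE)
  }
  invisible(bits)
}

#' Hamming distance between two antibodies
#'
#' @param a,b 0/1 vectors of equal length.
#' @return The count of differing positions.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) {
    stop("antibodies must have equal lengths", call. = FALSE)
  }
  sum(a != b)
}

#' Antibody-antibody affinity via Hamming distance
#'
#' `1 / (1 + hamming(a, b))`: 1 for identical antibodies, decreasing with
#' the number of differing bits. Used to measure crowding in the
#' thresholding optimizer.
#'
#' @inheritParams hamming
#' @return A value in (0, 1\].
#' @export
ab_affinity_hamming <- function(a, b) {
  1 / (1 + hamming(a, b))
}

#' Antibody concentration
#'
#' The fraction of the population whose pairwise affinity with antibody `i`
#' exceeds the affinity constant `lambda`; the antibody itself always counts,
#' so the result lies in \[1/N, 1\]. High concentration marks crowded regions
#' of the search space and is penalized by [adjusted_fitness()].
#'
#' @param pop Antibody group: a 0/1 matrix with one antibody per row.
#' @param i Row index of the antibody whose concentration is computed.
#' @param lambda Affinity constant in \[0.9, 1\].
#' @param pair_affinity Function of two antibodies returning their affinity;
#'   default [ab_affinity_hamming()].
#' @return Concentration in \[1/N, 1\].
#' @export
concentration <- function(pop, i, lambda, pair_affinity = ab_affinity_hamming) {
  if (!is.matrix(pop) || nrow(pop) == 0L) {
    stop("`pop` must be a non-empty antibody matrix", call. = FALSE)
  }
  if (!is_count(i) || i > nrow(pop)) stop("`i` out of range", call. = FALSE)
  n <- nrow(pop)
  aff <- vapply(seq_len(n), function(j) pair_affinity(pop[i, ], pop[j, ]),
                numeric(1))
  sum(aff > lambda) / n
}

# Vectorized pairwise-affinity matrices used inside the generation loop.
pairwise_affinity_hamming <- function(pop) {
  storage.mode(pop) <- "double"
  match_counts <- tcrossprod(pop) + tcrossprod(1 - pop)
  1 / (1 + (ncol(pop) - match_counts))
}

pairwise_affinity_euclid <- function(pop) {
  centers <- t(apply(pop, 1L, decode_gray))
  if (ncol(pop) == 8L) centers <- matrix(centers, ncol = 1L)
  1 / (1 + as.matrix(stats::dist(centers))^2)
}

concentration_all <- function(aff_matrix, lambda) {
  rowSums(aff_matrix > lambda) / nrow(aff_matrix)
}

#' Concentration-adjusted fitness
#'
#' Corrects the antigen affinity for crowding: `affinity * exp(k * D_i)` with
#' `k < 0`, so antibodies in dense regions of the population are demoted while
#' the ranking among antibodies of equal concentration is preserved.
#'
#' @param affinity Nonnegative antigen affinity (or a vector of them).
#' @param d_i Concentration(s) in \[0, 1\].
#' @param k Negative penalty constant; default -0.8.
#' @return Adjusted fitness value(s).
#' @export
adjusted_fitness <- function(affinity, d_i, k = -0.8) {
  if (any(affinity < 0)) stop("`affinity` must be nonnegative", call. = FALSE)
  if (k >= 0) stop("`k` must be negative", call. = FALSE)
  affinity * exp(k * d_i)
}

#' Rank-proportional clonal selection
#'
#' Sorts the population by fitness (descending, ties broken by original
#' index), keeps the top `m = ceiling(N/2)` antibodies, and clones the
#' antibody of rank `r` `max(1, round(mc / r))` times (half-up rounding).
#' The highest-fitness antibody is always present in the clone group.
#'
#' Clone rows are ordered round-robin over ranks (rank 1 copy 1, rank 2
#' copy 1, ..., rank 1 copy 2, ...) so that when the group is later
#' truncated to the population size, every selected rank stays represented
#' and the next generation keeps its diversity.
#'
#' @param pop Antibody matrix, one antibody per row.
#' @param fitnesses Fitness per antibody.
#' @param mc Clone count granted to rank 1; must not exceed the population size.
#' @return The clone group as a matrix; attribute `source` gives the
#'   originating row of each clone.
#' @export
clone_select <- function(pop, fitnesses, mc) {
  n <- nrow(pop)
  if (length(fitnesses) != n) {
    stop("`fitnesses` must have one value per antibody", call. = FALSE)
  }
  if (mc > n) stop("`mc` must not exceed the population size", call. = FALSE)
  ord <- order(fitnesses, decreasing = TRUE)  # stable: ties keep input order
  m <- ceiling(n / 2)
  sel <- ord[seq_len(m)]
  counts <- pmax(1, round_half_up(mc / seq_len(m)))
  rank <- rep(seq_len(m), times = counts)
  copy <- unlist(lapply(counts, seq_len))
  src <- rep(sel, times = counts)[order(copy, rank)]
  clones <- pop[src, , drop = FALSE]
  attr(clones, "source") <- src
  clones
}

#' Single-point crossover against a fresh random antibody group
#'
#' Each clone, with probability `qc`, exchanges its suffix from a uniformly
#' chosen cut position with a randomly generated partner antibody (partner
#' `i` pairs with clone `i`); otherwise it passes through unchanged. A cut at
#' the first position replaces the clone with its partner entirely.
#'
#' @param clones Clone group matrix.
#' @param qc Crossover probability in \[0, 1\].
#' @param partners Optional partner matrix of the same shape; by default a
#'   fresh uniform-random group is drawn from the current RNG stream.
#' @return The crossed group (same shape as `clones`).
#' @export
crossover <- function(clones, qc, partners = NULL) {
  if (!is.matrix(clones) || nrow(clones) == 0L) {
    stop("`clones` must be a non-empty antibody matrix", call. = FALSE)
  }
  n <- nrow(clones); l <- ncol(clones)
  if (is.null(partners)) {
    partners <- matrix(sample(c(0L, 1L), n * l, replace = TRUE), n, l)
  }
  do_cross <- stats::runif(n) < qc
  cuts <- sample.int(l, n, replace = TRUE)
  out <- clones
  for (i in which(do_cross)) {
    out[i, cuts[i]:l] <- partners[i, cuts[i]:l]
  }
  out
}

#' Single-bit mutation
#'
#' Each antibody, with probability `qm`, has exactly one uniformly chosen bit
#' flipped; otherwise it is unchanged. The output is therefore always within
#' Hamming distance 1 of the input, per antibody.
#'
#' @param group Antibody matrix.
#' @param qm Mutation probability in \[0, 1\].
#' @return The mutated group.
#' @export
mutate_antibodies <- function(group, qm) {
  if (!is.matrix(group) || nrow(group) == 0L) {
    stop("`group` must be a non-empty antibody matrix", call. = FALSE)
  }
  n <- nrow(group); l <- ncol(group)
  do_mut <- stats::runif(n) < qm
  pos <- sample.int(l, n, replace = TRUE)
  for (i in which(do_mut)) {
    group[i, pos[i]] <- 1L - group[i, pos[i]]
  }
  group
}

#' Stall termination rule
#'
#' Stops a run when the memory-cell affinity has not improved for
#' `stall_gens` consecutive generations.
#'
#' @param stall_gens Number of consecutive no-improvement generations.
#' @return A termination function for [run_immune()].
#' @export
stop_stall <- function(stall_gens) {
  function(state) {
    best <- state$trace_affinity
    g <- length(best)
    if (g <= stall_gens) return(FALSE)
    recent <- best[(g - stall_gens):g]
    max(recent) - min(recent) <= 1e-12
  }
}

#' Objective-stagnation termination rule
#'
#' Stops a run early only while the elite objective `J*` is still within
#' `j_tol` (default `rel * J1`) of the first-generation elite objective
#' `J1` -- i.e. the search has not meaningfully improved on its starting
#' point (a degenerate or already-solved problem). Once the elite moves
#' beyond the tolerance the run uses its full generation budget, letting
#' the global immune search keep exploring after the first local refinement.
#'
#' @param j_tol Absolute tolerance on `|J1 - J*|`, or `NULL` to use
#'   `rel * J1`.
#' @param rel Relative tolerance used when `j_tol` is `NULL`; default 1e-3.
#' @return A termination function for [run_immune()].
#' @export
stop_objective_delta <- function(j_tol = NULL, rel = 1e-3) {
  function(state) {
    tol <- if (is.null(j_tol)) rel * state$initial_objective else j_tol
    abs(state$initial_objective - state$best_objective) <= tol
  }
}

#' Run the clonal-selection optimizer
#'
#' Executes the generation loop: evaluate antigen affinity, update the memory
#' cell (elitist store of the best antibody ever evaluated), optionally refine
#' the memory cell with a local-search hook, compute concentrations and
#' adjusted fitness, clone by rank, cross against a fresh random group, apply
#' single-bit mutation, re-evaluate, and update the memory cell again. The
#' next generation is the mutated group truncated (or padded with random
#' antibodies) to `popsize`, with the memory cell re-injected in row 1 and,
#' following standard clonal-selection practice, the last 20% of slots
#' replaced by fresh random antibodies (receptor editing) to keep the
#' population from collapsing onto the elite.
#'
#' @param antigen_affinity Function mapping an antibody (0/1 vector of length
#'   `L`) to its nonnegative antigen affinity; higher is better.
#' @param L Antibody length in bits; a positive multiple of 8.
#' @param params An [immune_params()] object.
#' @param stop_rule Termination function taking the run state (fields
#'   `gen`, `trace_affinity`, `best_affinity`, `best_objective`,
#'   `initial_objective`) and returning `TRUE` to stop; default the stall rule.
#' @param pair_affinity Either `"hamming"` or `"euclid"` (affinity between
#'   decoded center sets), or a function mapping an antibody matrix to an
#'   N x N affinity matrix.
#' @param objective Optional function mapping an antibody to the objective
#'   value recorded in the trace (default: the antigen affinity itself).
#' @param refine Optional local-refinement hook: a function mapping the
#'   memory-cell antibody to a candidate antibody, adopted only if its
#'   affinity improves on the memory cell.
#' @return An object of class `immune_fit`: list with `bits` (best antibody),
#'   `affinity`, `objective`, `initial_objective` (first-generation elite
#'   objective), `generations`, and `trace` (a tibble of class `immune_trace`
#'   with columns generation, best_affinity, best_objective,
#'   mean_concentration).
#' @export
run_immune <- function(antigen_affinity, L, params,
                       stop_rule = stop_stall(params$stall_gens),
                       pair_affinity = "hamming",
                       objective = NULL, refine = NULL) {
  if (!is_count(L) || L %% 8L != 0L) {
    stop("`L` must be a positive multiple of 8", call. = FALSE)
  }
  if (!inherits(params, "immune_params")) {
    stop("`params` must be an immune_params object", call. = FALSE)
  }
  pair_fun <- if (is.function(pair_affinity)) {
    pair_affinity
  } else {
    switch(match.arg(pair_affinity, c("hamming", "euclid")),
           hamming = pairwise_affinity_hamming,
           euclid = pairwise_affinity_euclid)
  }
  if (is.null(objective)) objective <- antigen_affinity

  eval_affinity <- function(group) {
    aff <- apply(group, 1L, antigen_affinity)
    bad <- which(!is.finite(aff))
    if (length(bad)) {
      stop(sprintf("non-finite affinity for antibody decoding to [%s]",
                   paste(decode_gray(group[bad[1], ]), collapse = ", ")),
           call. = FALSE)
    }
    aff
  }

  with_seed(params$seed, {
    pop <- matrix(sample(c(0L, 1L), params$popsize * L, replace = TRUE),
                  params$popsize, L)
    memory <- NULL
    initial_objective <- NA_real_
    tr_gen <- integer(0); tr_aff <- numeric(0)
    tr_obj <- numeric(0); tr_conc <- numeric(0)

    update_memory <- function(group, aff) {
      b <- which.max(aff)
      if (is.null(memory) || aff[b] > memory$affinity) {
        memory <<- list(bits = group[b, ], affinity = aff[b],
                        objective = objective(group[b, ]))
      }
    }

    gen <- 0L
    for (g in seq_len(params$maxgen)) {
      gen <- g
      aff <- eval_affinity(pop)
      update_memory(pop, aff)
      if (g == 1L) initial_objective <- memory$objective

      if (!is.null(refine)) {
        cand <- refine(memory$bits)
        if (!is.null(cand)) {
          cand_aff <- antigen_affinity(cand)
          if (is.finite(cand_aff) && cand_aff > memory$affinity) {
            memory <- list(bits = cand, affinity = cand_aff,
                           objective = objective(cand))
          }
        }
      }

      d <- concentration_all(pair_fun(pop), params$lambda)
      fit <- adjusted_fitness(aff, d, params$k)

      tr_gen <- c(tr_gen, g)
      tr_aff <- c(tr_aff, memory$affinity)
      tr_obj <- c(tr_obj, memory$objective)
      tr_conc <- c(tr_conc, mean(d))

      state <- list(gen = g, trace_affinity = tr_aff,
                    best_affinity = memory$affinity,
                    best_objective = memory$objective,
                    initial_objective = initial_objective)
      if (isTRUE(stop_rule(state))) break
      if (g == params$maxgen) break

      clones <- clone_select(pop, fit, params$mc)
      crossed <- crossover(clones, params$qc)
      mutated <- mutate_antibodies(crossed, params$qm)
      maff <- eval_affinity(mutated)
      update_memory(mutated, maff)

      if (nrow(mutated) >= params$popsize) {
        pop <- mutated[seq_len(params$popsize), , drop = FALSE]
      } else {
        pad <- matrix(sample(c(0L, 1L), (params$popsize - nrow(mutated)) * L,
                             replace = TRUE),
                      params$popsize - nrow(mutated), L)
        pop <- rbind(mutated, pad)
      }
      pop[1L, ] <- memory$bits
      n_new <- max(1L, as.integer(round_half_up(0.2 * params$popsize)))
      pop[(params$popsize - n_new + 1L):params$popsize, ] <-
        matrix(sample(c(0L, 1L), n_new * L, replace = TRUE), n_new, L)
    }

    trace <- tibble::new_tibble(
      list(generation = tr_gen, best_affinity = tr_aff,
           best_objective = tr_obj, mean_concentration = tr_conc),
      class = "immune_trace")
    structure(
      list(bits = memory$bits, affinity = memory$affinity,
           objective = memory$objective,
           initial_objective = initial_objective,
           generations = gen, trace = trace),
      class = "immune_fit")
  })
}

#' @export
print.immune_fit <- function(x, ...) {
  cat(sprintf("<immune_fit> %d generations, best affinity %.6g, objective %.6g\n",
              x$generations, x$affinity, x$objective))
  invisible(x)
}

#' Write a convergence trace to CSV
#'
#' @param trace An `immune_trace` tibble (from an `immune_fit`,
#'   [aia_threshold()] or [ica_segment()] result).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
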