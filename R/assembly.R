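pair_table_cols <- c("species_1", "species_2", "category", "f_12")

check_pair_table <- function(pair_table) {
  missing <- setdiff(pair_table_cols, names(pair_table))
  if (length(missing))
    stop("pairwise outcome table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ok_cat <- c("coexistence", "bistability", "species_1_excludes_2",
              "species_2_excludes_1", "no_survivors", "degenerate")
  bad <- setdiff(unique(pair_table$category), ok_cat)
  if (length(bad))
    stop("unknown pair categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  f <- pair_table$f_12
  co <- pair_table$category == "coexistence"
  if (any(co & (!is.finite(f) | f <= 0 | f >= 1)))
    stop("coexistence rows need an interior f_12 in (0, 1)", call. = FALSE)
  invisible(pair_table)
}

#' Build a pairwise outcome table from outcome calls
#'
#' Collects [call_pair_outcome()] results (or classifications from the model
#' side) into the tabular form consumed by the assembly rules: one row per
#' unordered pair per dilution factor, with the qualitative category and the
#' equilibrium fraction `f_12` of `species_1` on the coexistence branch.
#'
#' @param calls List of `outcome_call` objects.
#' @return Data frame with columns `species_1`, `species_2`,
#'   `dilution_factor`, `category`, `f_12`.
#' @export
pair_outcome_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    data.frame(species_1 = cl$species[1], species_2 = cl$species[2],
               dilution_factor = cl$dilution_factor,
               category = cl$category,
               f_12 = if (cl$category == "coexistence") cl$stable_fraction
                      else if (cl$category == "species_1_excludes_2") 1
                      else if (cl$category == "species_2_excludes_1") 0
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# lookup helpers over an (unordered-pair) table ------------------------------

pair_row <- function(pair_table, a, b) {
  hit <- (pair_table$species_1 == a & pair_table$species_2 == b) |
    (pair_table$species_1 == b & pair_table$species_2 == a)
  if (sum(hit) != 1)
    stop("pairwise table must contain exactly one row for pair (", a, ", ",
         b, "); found ", sum(hit), call. = FALSE)
  pair_table[hit, , drop = FALSE]
}

# fraction of species a in the (a, b) coculture at coexistence
pair_fraction <- function(pair_table, a, b) {
  row <- pair_row(pair_table, a, b)
  if (row$species_1 == a) row$f_12 else 1 - row$f_12
}

# TRUE when species `loser` can be excluded by `winner` on some branch
excludes_on_some_branch <- function(pair_table, winner, loser) {
  row <- pair_row(pair_table, winner, loser)
  if (row$category == "bistability") return(TRUE)
  if (row$category == "no_survivors") return(TRUE)
  if (row$category == "species_1_excludes_2") return(row$species_1 == winner)
  if (row$category == "species_2_excludes_1") return(row$species_2 == winner)
  FALSE
}

pair_category <- function(pair_table, a, b) pair_row(pair_table, a, b)$category

#' Enumerate the survivor sets allowed by the pairwise assembly rules
#'
#' The assembly rules state that a species survives in a multispecies
#' community if and only if it coexists in pairwise coculture with every
#' other survivor. A candidate set S is therefore allowed when (i) every pair
#' inside S coexists (a bistable pair has no branch on which both members
#' survive, so it disqualifies S), and (ii) every species outside S is
#' excluded by at least one member of S on some branch -- via an outright
#' exclusion, or via the losing branch of a bistable pair. Bistable pairs can
#' make several sets allowed at once, the multispecies analogue of
#' bistability.
#'
#' @param pair_table Pairwise outcome table (see [pair_outcome_table()])
#'   covering all pairs among `species`.
#' @param species Character vector of candidate species.
#' @param dilution_factor Optional filter applied to the table before
#'   enumeration.
#' @param viable Optional named logical: species whose monocultures die at
#'   this dilution factor (`FALSE`) are barred from survivor sets and need no
#'   pairwise excluder. Defaults to all viable.
#' @return List of allowed survivor sets (character vectors), largest first.
#'   An empty list (with a warning) signals a non-transitive topology with no
#'   self-consistent state.
#' @export
allowed_survivor_sets <- function(pair_table, species, dilution_factor = NULL,
                                  viable = NULL) {
  if (!is.null(dilution_factor))
    pair_table <- pair_table[pair_table$dilution_factor == dilution_factor, ,
                             drop = FALSE]
  check_pair_table(pair_table)
  if (is.null(viable)) viable <- stats::setNames(rep(TRUE, length(species)),
                                                 species)
  species <- sort(species)
  n <- length(species)
  allowed <- list()
  for (mask in seq_len(2^n) - 1L) {
    S <- species[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (!length(S)) next
    if (!all(viable[S])) next
    inside_ok <- TRUE
    if (length(S) > 1) {
      combs <- utils::combn(S, 2)
      inside_ok <- all(apply(combs, 2, function(p)
        pair_category(pair_table, p[1], p[2]) == "coexistence"))
    }
    if (!inside_ok) next
    outside <- setdiff(species, S)
    outside_ok <- all(vapply(outside, function(k) {
      !viable[k] || any(vapply(S, function(s)
        excludes_on_some_branch(pair_table, s, k), logical(1)))
    }, logical(1)))
    if (outside_ok) allowed[[length(allowed) + 1]] <- S
  }
  if (!length(allowed))
    warning("no survivor set is consistent with the pairwise outcomes ",
            "(non-transitive exclusion topology)", call. = FALSE)
  allowed[order(-lengths(allowed),
                vapply(allowed, paste, character(1), collapse = "+"))]
}

#' Predict multispecies composition from pairwise coexisting fractions
#'
#' For a surviving set S the predicted fraction of each member is built from
#' its pairwise equilibrium fractions: a pair's prediction is its coculture
#' fraction verbatim, and for three or more survivors each species gets the
#' weighted geometric mean of its pairwise fractions,
#' `f_i = (prod_j f_ij^w_j)^(1/sum_j w_j)`, where the weight of opponent `j`
#' is the geometric mean of j's own pairwise fractions within S
#' (`w_2 = sqrt(f_21 f_23)` in a trio). The f's are then normalized to sum
#' to one. For sets of four or more the same geometric-mean weighting is
#' applied over all of a species' opponents; note this is an extrapolation of
#' the printed trio weighting to larger sets.
#'
#' @param survivors Character vector S of surviving species.
#' @param pair_table Pairwise outcome table; every pair within S must carry a
#'   coexistence fraction in (0, 1), otherwise S was not a valid coexisting
#'   set and an error is raised.
#' @param species Full species list over which the composition is expressed
#'   (non-survivors get 0). Defaults to `survivors`.
#' @param dilution_factor Optional filter applied to the table.
#' @return Named composition vector over `species`, summing to 1.
#' @export
predict_fractions <- function(survivors, pair_table, species = survivors,
                              dilution_factor = NULL) {
  if (!is.null(dilution_factor))
    pair_table <- pair_table[pair_table$dilution_factor == dilution_factor, ,
                             drop = FALSE]
  if (!all(survivors %in% species))
    stop("survivors must be a subset of species", call. = FALSE)
  comp <- stats::setNames(numeric(length(species)), species)
  S <- survivors
  if (length(S) == 0) stop("empty survivor set", call. = FALSE)
  if (length(S) == 1) {
    comp[S] <- 1
    return(comp)
  }
  fmat <- outer(S, S, Vectorize(function(a, b) {
    if (a == b) return(NA_real_)
    pair_fraction(pair_table, a, b)
  }))
  dimnames(fmat) <- list(S, S)
  off <- fmat[!is.na(fmat)]
  if (any(!is.finite(off) | off <= 0 | off >= 1))
    stop("all pairs within the survivor set must coexist with interior ",
         "fractions; got a boundary or missing fraction", call. = FALSE)
  if (length(S) == 2) {
    comp[S] <- c(fmat[1, 2], fmat[2, 1])
    return(comp)
  }
  # w_j: geometric mean of j's pairwise fractions against the rest of S
  w <- vapply(S, function(j) {
    others <- setdiff(S, j)
    prod(fmat[j, others])^(1 / length(others))
  }, numeric(1))
  f <- vapply(S, function(i) {
    others <- setdiff(S, i)
    exp(sum(w[others] * log(fmat[i, others])) / sum(w[others]))
  }, numeric(1))
  comp[S] <- f / sum(f)
  comp
}

#' All allowed states with their predicted compositions
#'
#' Convenience wrapper running [allowed_survivor_sets()] and
#' [predict_fractions()] for one community at one dilution factor.
#'
#' @inheritParams allowed_survivor_sets
#' @return List with `states` (allowed survivor sets) and `compositions`
#'   (predicted composition per state over `species`); zero-length when no
#'   state is allowed.
#' @export
assembly_prediction <- function(pair_table, species, dilution_factor = NULL,
                                viable = NULL) {
  states <- allowed_survivor_sets(pair_table, species, dilution_factor,
                                  viable)
  compositions <- lapply(states, predict_fractions, pair_table = pair_table,
                         species = species, dilution_factor = dilution_factor)
  list(states = states, compositions = compositions)
}

#' Carrying-capacity (monoculture) baseline prediction
#'
#' The null prediction that every species always coexists and grows to a
#' density proportional to its monoculture carrying capacity at that
#' dilution factor; species extinct in monoculture contribute zero.
#'
#' @param densities Named nonnegative vector of monoculture endpoint
#'   densities (e.g. CFU/ml), one per species; 0 for species extinct in
#'   monoculture.
#' @return Named composition vector proportional to `densities`.
#' @export
carrying_capacity_prediction <- function(densities) {
  if (any(!is.finite(densities)) || any(densities < 0))
    stop("densities must be finite and nonnegative", call. = FALSE)
  if (sum(densities) == 0)
    stop("all species extinct in monoculture: no carrying-capacity ",
         "prediction is defined", call. = FALSE)
  densities / sum(densities)
}

#' Random baseline composition
#'
#' A draw from the flat (uniform) distribution on the simplex, the
#' no-information baseline against which structured predictions are scored.
#'
#' @param n Number of species (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return Composition vector of length `n` summing to 1.
#' @export
random_prediction <- function(n, seed = NULL) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  x <- stats::rexp(n)  # normalized iid exponentials are flat on the simplex
  x / sum(x)
}
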