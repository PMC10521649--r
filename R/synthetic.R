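#' Replace a reaction's standard Gibbs energy (thermodynamic blocking)
#'
#' Setting a strongly positive value (e.g. +40 RT, beyond any
#' concentration-box span) renders every route through the reaction
#' thermodynamically infeasible, emulating pathway-level barriers such as
#' the one at 3-phosphoglycerate dehydrogenase.
#'
#' @param network A `metabolic_network`.
#' @param reaction_id Reaction to alter.
#' @param g0_RT New standard Gibbs energy in RT units.
#' @param temperature_K Temperature for the RT -> kJ/mol conversion.
#' @return A copy of the network with the value replaced.
#' @export
block_thermodynamically <- function(network, reaction_id, g0_RT,
                                    temperature_K = 298.15) {
  if (is.null(network$reactions[[reaction_id]]))
    stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  network$reactions[[reaction_id]]$delta_g <- g0_RT * R_GAS * temperature_K
  network
}

#' Generate a network with a planted unique shortest pathway
#'
#' Builds a linear source-to-sink chain of `path_length` irreversible
#' reactions with comfortably exergonic standard energies (uniform on
#' [-5, -1] RT), then adds random distractor reactions one at a time,
#' accepting a candidate only if the brute-force oracle confirms that the
#' planted chain is still the unique minimum-cardinality feasible route.
#' Deterministic for a fixed seed.
#'
#' @param n_metabolites Total metabolite count (>= path_length + 1).
#' @param n_distractors Number of distractor reactions to add.
#' @param path_length Planted chain length (>= 1).
#' @param seed Integer RNG seed.
#' @param beta Flux cap used in the oracle checks.
#' @param max_attempts Rejection budget per distractor.
#' @return A list of class `"planted_network"` with fields `network`,
#'   `planted_path`, `source`, `sink`, `seed`, `n_distractors`.
#' @export
generate_planted_network <- function(n_metabolites, n_distractors, path_length,
                                     seed, beta = 10, max_attempts = 200L) {
  if (path_length < 1) stop("path_length must be >= 1", call. = FALSE)
  if (n_metabolites < path_length + 1)
    stop("need at least path_length + 1 metabolites", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  met_ids <- paste0("m", seq_len(n_metabolites))
  mets <- lapply(met_ids, metabolite)
  rt_kj <- R_GAS * 298.15
  planted <- character(path_length)
  rxns <- list()
  for (k in seq_len(path_length)) {
    id <- paste0("P", k)
    planted[k] <- id
    st <- stats::setNames(c(-1, 1), met_ids[c(k, k + 1)])
    rxns[[id]] <- reaction(id, st, delta_g = stats::runif(1, -5, -1) * rt_kj)
  }
  source <- met_ids[1]; sink <- met_ids[path_length + 1]
  net <- metabolic_network(mets, rxns, check_elements = NULL)
  oracle_ok <- function(candidate_net) {
    res <- planted_min_sets(candidate_net, source, sink, beta = beta,
                            max_cardinality = path_length)
    length(res) == 1L &&
      setequal(sub("_fwd$", "", res[[1]]), planted)
  }
  added <- 0L; attempts <- 0L
  while (added < n_distractors) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("planted-network generation failed after ", max_attempts,
           " rejection attempts", call. = FALSE)
    n_sub <- sample(1:2, 1); n_prod <- sample(1:2, 1)
    picked <- sample(met_ids, n_sub + n_prod)
    st <- stats::setNames(c(rep(-1, n_sub), rep(1, n_prod)), picked)
    id <- paste0("D", added + 1L)
    cand <- reaction(id, st, delta_g = stats::runif(1, -5, -1) * rt_kj)
    trial <- net
    trial$reactions[[id]] <- cand
    if (oracle_ok(trial)) {
      net <- trial
      added <- added + 1L
    }
  }
  structure(list(network = net, planted_path = planted, source = source,
                 sink = sink, seed = seed, n_distractors = n_distractors),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat("Planted network (seed ", x$seed, "): ", length(x$network$reactions),
      " reactions, planted ", x$source, " -> ", x$sink, " path of length ",
      length(x$planted_path), "\n", sep = "")
  invisible(x)
}

#' Generate disjoint parallel routes between one source and one sink
#'
#' Every route uses its own private intermediates, so the indicator
#' vectors of any two routes differ in `2 * route_length` positions --
#' a controlled instance for exercising the integer-cut stopping rule.
#'
#' @param n_routes Number of parallel routes.
#' @param route_length Reactions per route (>= 1).
#' @param g0_RT Standard energy (RT units) given to every reaction.
#' @return A `metabolic_network` with source `"src"` and sink `"snk"`.
#' @export
generate_parallel_routes <- function(n_routes = 12L, route_length = 3L,
                                     g0_RT = -5) {
  rt_kj <- R_GAS * 298.15
  mets <- list(metabolite("src"), metabolite("snk"))
  rxns <- list()
  for (r in seq_len(n_routes)) {
    chain <- c("src", if (route_length > 1)
      paste0("i", r, "_", seq_len(route_length - 1)), "snk")
    for (m in setdiff(chain, c("src", "snk")))
      mets[[length(mets) + 1L]] <- metabolite(m)
    for (k in seq_len(route_length)) {
      id <- sprintf("R%d_%d", r, k)
      st <- stats::setNames(c(-1, 1), chain[c(k, k + 1)])
      rxns[[id]] <- reaction(id, st, delta_g = g0_RT * rt_kj)
    }
  }
  metabolic_network(mets, rxns, check_elements = NULL)
}

# objective + split + default thermo for a plain source -> sink search
planted_directed <- function(network, source, sink, beta = 10) {
  with_obj <- add_objective_reaction(
    network, objective_spec(source = source, sink = sink, atp_yield = 0L))
  directed <- split_reactions(with_obj, beta = beta)
  list(directed = directed, thermo = thermo_params(directed))
}

planted_min_sets <- function(network, source, sink, beta = 10,
                             max_cardinality = 6L) {
  parts <- planted_directed(network, source, sink, beta)
  brute_force_enumerate(parts$directed, parts$thermo,
                        max_cardinality = max_cardinality)
}

#' Brute-force enumeration oracle
#'
#' Exhaustively tests directed-reaction subsets in order of increasing
#' cardinality. A subset is feasible iff (a) a linear program finds rates
#' in `[flux_epsilon, beta]` for the subset that balance every metabolite
#' against the objective reaction at rate -1, and (b) a second linear
#' program finds in-box log-concentrations giving every subset reaction a
#' non-negative driving force. Both LPs run on a plain simplex
#' implementation, independent of the MILP backend. Returns all
#' minimum-cardinality feasible subsets.
#'
#' @param directed A `directed_network` (at most 20 directed reactions).
#' @param thermo A [thermo_params()] object.
#' @param max_cardinality Largest subset size to try.
#' @param flux_epsilon Minimum rate per subset member.
#' @return List of character vectors (directed-reaction ids); empty when
#'   no feasible subset exists within the cardinality limit.
#' @export
brute_force_enumerate <- function(directed, thermo, max_cardinality = 6L,
                                  flux_epsilon = 1e-3) {
  ids <- names(directed$reactions)
  if (length(ids) > 20L)
    stop("oracle guard: more than 20 directed reactions", call. = FALSE)
  ob <- directed$objective$stoich
  source_id <- names(ob)[ob < 0][1]
  sink_id <- names(ob)[ob > 0][1]
  consumes_source <- vapply(directed$reactions, function(d)
    source_id %in% names(d$stoich) && d$stoich[[source_id]] < 0, logical(1))
  produces_sink <- vapply(directed$reactions, function(d)
    sink_id %in% names(d$stoich) && d$stoich[[sink_id]] > 0, logical(1))
  pair_of <- lapply(directed$pairing, function(p) if (length(p) == 2L) unname(p))
  pair_of <- Filter(Negate(is.null), pair_of)

  for (k in seq_len(min(max_cardinality, length(ids)))) {
    found <- list()
    combos <- utils::combn(length(ids), k, simplify = FALSE)
    for (sel in combos) {
      sub <- ids[sel]
      if (!any(consumes_source[sel]) || !any(produces_sink[sel])) next
      if (any(vapply(pair_of, function(p) all(p %in% sub), logical(1)))) next
      if (!flux_feasible(directed, sub, flux_epsilon)) next
      if (!thermo_feasible(directed, thermo, sub)) next
      found[[length(found) + 1L]] <- sub
    }
    if (length(found)) return(found)
  }
  list()
}

# LP (a): exists v in [eps, beta]^A with S_A v = s_obj?
# Solved in elastic form (minimise total slack); feasible iff slack ~ 0.
# Variables are shifted to w = v - eps >= 0 and bounds folded into
# inequality rows (the simplex here assumes non-negative variables).
flux_feasible <- function(directed, sub, flux_epsilon, tol = 1e-7) {
  met_ids <- metabolite_ids(directed)
  S <- matrix(0, length(met_ids), length(sub),
              dimnames = list(met_ids, sub))
  for (id in sub) {
    d <- directed$reactions[[id]]
    S[names(d$stoich), id] <- d$stoich
  }
  rows <- rowSums(S != 0) > 0
  ob <- directed$objective$stoich
  rhs <- stats::setNames(rep(0, length(met_ids)), met_ids)
  rhs[names(ob)] <- ob
  if (any(abs(rhs[!rows]) > 0)) return(FALSE)  # objective metabolite untouched
  S <- S[rows, , drop = FALSE]; rhs <- rhs[rows]
  m <- nrow(S); n <- ncol(S)
  Aeq <- cbind(S, diag(m), -diag(m))
  beq <- unname(rhs) - rowSums(S) * flux_epsilon
  A <- cbind(diag(n), matrix(0, n, 2 * m))     # w <= beta - eps
  b <- rep(directed$beta - flux_epsilon, n)
  cc <- c(rep(0, n), rep(1, 2 * m))
  res <- tryCatch(
    pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq, maxiter = 500),
    error = function(e) NULL)
  !is.null(res) && !is.null(res$x) && res$fval < tol
}

# LP (b): exists x in the box with driving force >= 0 for every member?
# Maximise the worst-case slack t; feasible iff optimal t >= 0. Shifted to
# non-negative variables: y = x - ln_c_min, u = t + T_SHIFT.
thermo_feasible <- function(directed, thermo, sub, tol = 1e-9) {
  cons <- list()
  mets <- character()
  for (id in sub) {
    d <- directed$reactions[[id]]
    if (is.na(thermo$g0[[id]])) next
    ids <- setdiff(names(d$stoich), thermo$exempt)
    cons[[length(cons) + 1L]] <- list(st = d$stoich[ids], g0 = thermo$g0[[id]])
    mets <- union(mets, ids)
  }
  if (!length(cons)) return(TRUE)
  p <- length(mets)
  t_shift <- 1e3
  lo <- thermo$ln_c_min[mets]
  span <- thermo$ln_c_max[mets] - lo
  A <- matrix(0, length(cons), p + 1, dimnames = list(NULL, c(mets, ".u")))
  b <- numeric(length(cons))
  for (i in seq_along(cons)) {
    st <- cons[[i]]$st
    A[i, names(st)] <- st
    A[i, p + 1] <- 1
    b[i] <- -cons[[i]]$g0 - sum(st * lo[names(st)]) + t_shift
  }
  A <- rbind(A, diag(p + 1))                   # y <= span, u <= 2 * t_shift
  b <- c(b, unname(span), 2 * t_shift)
  cc <- c(rep(0, p), -1)                       # maximise u
  res <- tryCatch(
    pracma::linprog(cc, A = A, b = b, maxiter = 500),
    error = function(e) NULL)
  !is.null(res) && !is.null(res$x) && res$x[p + 1] - t_shift >= -tol
}
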