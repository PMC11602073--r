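#' Define a node of the dynamic Bayesian network
#'
#' @param name Node name.
#' @param states Ordered character vector of at least two state labels.
#' @param parents Same-slice parent node names (order fixes CPT row indexing).
#' @param temporal_parents Previous-slice parent node names.
#' @param cpt Numeric matrix: one column per state, one row per combination of
#'   parent states. Rows are indexed with the *first* parent varying fastest
#'   (same-slice parents first, then temporal parents), i.e. the
#'   `expand.grid` convention. Each row must sum to 1.
#' @return A list of class `dbn_node`.
#' @export
dbn_node <- function(name, states, parents = character(),
                     temporal_parents = character(), cpt) {
  cpt <- as.matrix(cpt)
  structure(list(name = name, states = as.character(states),
                 parents = as.character(parents),
                 temporal_parents = as.character(temporal_parents),
                 cpt = cpt),
            class = "dbn_node")
}

# paste0 pads zero-length inputs to ""; this keeps them empty
suffix_each <- function(x, suffix) {
  if (!length(x)) character(0) else paste0(x, suffix)
}

# Index into a node's CPT rows given integer state indices of its parents
# (columns of `idx` in parent order). First parent varies fastest.
cpt_row_index <- function(parent_cards, idx) {
  if (length(parent_cards) == 0L) return(rep(1L, max(1L, nrow(idx))))
  mult <- cumprod(c(1L, parent_cards[-length(parent_cards)]))
  as.integer(1L + as.matrix(idx - 1L) %*% mult)
}

#' Assemble and validate a dynamic Bayesian network specification
#'
#' A first-order DBN at discrete (monthly) slices: each node has same-slice
#' parents and optionally previous-slice (temporal) parents. Validation
#' checks: CPT rows sum to 1 within 1e-9 and have the right count; the
#' same-slice graph is acyclic; all parents are declared nodes; evidence nodes
#' are parentless roots (which guarantees filtered and smoothed marginals
#' coincide). Interface nodes — those with outgoing temporal arcs — are
#' derived, not declared.
#'
#' @param nodes List of [dbn_node()] objects.
#' @param evidence_nodes Character vector of node names observed each slice.
#' @return An object of class `dbn_spec` with elements `nodes` (named list),
#'   `evidence_nodes`, `interface_nodes`, `topo_order`.
#' @export
dbn_spec <- function(nodes, evidence_nodes = character()) {
  names(nodes) <- vapply(nodes, function(n) n$name, character(1))
  if (anyDuplicated(names(nodes))) {
    stop("duplicate node names", call. = FALSE)
  }
  all_names <- names(nodes)

  for (nd in nodes) {
    if (length(nd$states) < 2) {
      stop(sprintf("node '%s': needs at least 2 states", nd$name), call. = FALSE)
    }
    undecl <- setdiff(c(nd$parents, nd$temporal_parents), all_names)
    if (length(undecl)) {
      stop(sprintf("node '%s': undeclared parent(s): %s", nd$name,
                   paste(undecl, collapse = ", ")), call. = FALSE)
    }
    cards <- vapply(c(nd$parents, nd$temporal_parents),
                    function(p) length(nodes[[p]]$states), integer(1))
    want_rows <- prod(c(1L, cards))
    if (nrow(nd$cpt) != want_rows || ncol(nd$cpt) != length(nd$states)) {
      stop(sprintf("node '%s': CPT is %dx%d, expected %dx%d",
                   nd$name, nrow(nd$cpt), ncol(nd$cpt), want_rows,
                   length(nd$states)), call. = FALSE)
    }
    if (any(nd$cpt < 0)) {
      stop(sprintf("node '%s': negative CPT entries", nd$name), call. = FALSE)
    }
    bad <- which(abs(rowSums(nd$cpt) - 1) > 1e-9)
    if (length(bad)) {
      stop(sprintf("node '%s': CPT row %d sums to %.6f, not 1",
                   nd$name, bad[1], rowSums(nd$cpt)[bad[1]]), call. = FALSE)
    }
  }

  # topological order of the same-slice graph (Kahn); cycle -> error
  remaining <- all_names
  parents_of <- lapply(nodes, function(n) n$parents)
  topo <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      length(intersect(parents_of[[n]], remaining)) == 0L
    }, logical(1))]
    if (!length(ready)) {
      stop(sprintf("intra-slice cycle among: %s",
                   paste(remaining, collapse = ", ")), call. = FALSE)
    }
    topo <- c(topo, ready)
    remaining <- setdiff(remaining, ready)
  }

  evidence_nodes <- as.character(evidence_nodes)
  miss <- setdiff(evidence_nodes, all_names)
  if (length(miss)) {
    stop(sprintf("unknown evidence node(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (e in evidence_nodes) {
    if (length(nodes[[e]]$parents) || length(nodes[[e]]$temporal_parents)) {
      stop(sprintf("evidence node '%s' must be a parentless root", e),
           call. = FALSE)
    }
  }

  interface_nodes <- all_names[all_names %in%
    unique(unlist(lapply(nodes, function(n) n$temporal_parents)))]
  if (!length(interface_nodes)) {
    interface_nodes <- character(0)
  }
  structure(list(nodes = nodes, evidence_nodes = evidence_nodes,
                 interface_nodes = interface_nodes, topo_order = topo),
            class = "dbn_spec")
}

#' @export
print.dbn_spec <- function(x, ...) {
  cat(sprintf("Dynamic Bayesian network: %d nodes\n", length(x$nodes)))
  for (nd in x$nodes[x$topo_order]) {
    tag <- if (nd$name %in% x$evidence_nodes) " [evidence]"
           else if (nd$name %in% x$interface_nodes) " [interface]"
           else ""
    tpar <- if (length(nd$temporal_parents)) {
      paste0(nd$temporal_parents, "(t-1)")
    } else character(0)
    par <- paste(c(nd$parents, tpar), collapse = ", ")
    cat(sprintf("  %s {%s}%s%s\n", nd$name,
                paste(nd$states, collapse = ", "),
                if (nzchar(par)) paste0(" <- ", par) else "", tag))
  }
  invisible(x)
}

node_cards <- function(dbn, names) {
  vapply(names, function(n) length(dbn$nodes[[n]]$states), integer(1))
}

#' Read a DBN specification from a YAML document
#'
#' The document has a top-level `evidence_nodes` list and a `nodes` mapping;
#' each node carries `states`, `parents`, `temporal_parents` and a `cpt` list
#' whose entries pair a `given` mapping (parent name -> state; temporal
#' parents suffixed `_prev`) with a probability vector `p` over the node's
#' states. Row order in the file is free; every parent-state combination must
#' appear exactly once.
#'
#' @param path Path to the YAML file.
#' @return A validated [dbn_spec()].
#' @export
read_dbn_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$nodes)) stop("malformed DBN spec: no 'nodes'", call. = FALSE)
  # first pass: states only, needed to size CPTs
  states_of <- lapply(doc$nodes, function(n) as.character(n$states))
  nodes <- lapply(names(doc$nodes), function(nm) {
    n <- doc$nodes[[nm]]
    parents <- as.character(unlist(n$parents))
    tparents <- as.character(unlist(n$temporal_parents))
    pkeys <- c(parents, suffix_each(tparents, "_prev"))
    pstates <- c(lapply(parents, function(p) states_of[[p]]),
                 lapply(tparents, function(p) states_of[[p]]))
    cards <- vapply(pstates, length, integer(1))
    want_rows <- prod(c(1L, cards))
    cpt <- matrix(NA_real_, nrow = want_rows, ncol = length(n$states))
    seen <- logical(want_rows)
    for (entry in n$cpt) {
      given <- entry$given
      if (length(pkeys)) {
        idx <- vapply(seq_along(pkeys), function(j) {
          val <- given[[pkeys[j]]]
          if (is.null(val)) {
            stop(sprintf("node '%s': CPT row missing parent '%s'", nm, pkeys[j]),
                 call. = FALSE)
          }
          pos <- match(val, pstates[[j]])
          if (is.na(pos)) {
            stop(sprintf("node '%s': unknown state '%s' for parent '%s'",
                         nm, val, pkeys[j]), call. = FALSE)
          }
          pos
        }, integer(1))
        row <- cpt_row_index(cards, matrix(idx, nrow = 1))
      } else {
        row <- 1L
      }
      if (seen[row]) {
        stop(sprintf("node '%s': duplicate CPT row", nm), call. = FALSE)
      }
      seen[row] <- TRUE
      cpt[row, ] <- as.numeric(unlist(entry$p))
    }
    if (!all(seen)) {
      stop(sprintf("node '%s': %d CPT row(s) missing", nm, sum(!seen)),
           call. = FALSE)
    }
    dbn_node(nm, n$states, parents, tparents, cpt)
  })
  dbn_spec(nodes, as.character(unlist(doc$evidence_nodes)))
}

#' Write a DBN specification as YAML
#'
#' Emits the same dialect accepted by [read_dbn_spec()], so specs round-trip.
#' @param dbn A `dbn_spec`.
#' @param path Output path.
#' @export
write_dbn_spec <- function(dbn, path) {
  doc <- list(evidence_nodes = as.list(dbn$evidence_nodes), nodes = list())
  for (nd in dbn$nodes[dbn$topo_order]) {
    pkeys <- c(nd$parents, suffix_each(nd$temporal_parents, "_prev"))
    pstates <- c(lapply(nd$parents, function(p) dbn$nodes[[p]]$states),
                 lapply(nd$temporal_parents, function(p) dbn$nodes[[p]]$states))
    grid <- if (length(pstates)) {
      expand.grid(pstates, stringsAsFactors = FALSE)
    } else data.frame(row.names = 1)
    rows <- lapply(seq_len(nrow(nd$cpt)), function(r) {
      given <- if (length(pkeys)) {
        stats::setNames(as.list(unlist(grid[r, , drop = TRUE])), pkeys)
      } else stats::setNames(list(), character(0))
      list(given = given, p = as.list(unname(nd$cpt[r, ])))
    })
    doc$nodes[[nd$name]] <- list(
      states = as.list(nd$states),
      parents = as.list(nd$parents),
      temporal_parents = as.list(nd$temporal_parents),
      cpt = rows
    )
  }
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

# Shoot-density transition rows without heat stress, keyed by previous density
# and an improvement score s = (#growth high) + (#seed yes). Rows favour
# persistence; the zero state is near-absorbing but recoverable through seed
# recruitment.
.sd_base_rows <- function() {
  list(
    high = rbind(c(0.45, 0.40, 0.12, 0.03),
                 c(0.75, 0.20, 0.04, 0.01),
                 c(0.92, 0.06, 0.015, 0.005)),
    moderate = rbind(c(0.05, 0.45, 0.40, 0.10),
                     c(0.20, 0.55, 0.20, 0.05),
                     c(0.45, 0.45, 0.08, 0.02)),
    low = rbind(c(0.01, 0.10, 0.54, 0.35),
                c(0.05, 0.25, 0.50, 0.20),
                c(0.15, 0.40, 0.35, 0.10)),
    zero = rbind(c(0.001, 0.009, 0.09, 0.90),
                 c(0.005, 0.045, 0.25, 0.70),
                 c(0.02, 0.13, 0.35, 0.50))
  )
}

#' The bundled seagrass resilience network
#'
#' A monthly-slice DBN realising the two heatwave mechanisms: temperature
#' (optimal/sub-optimal) drives physiological status and seed recruitment,
#' while heat stress (none/present) drives shoot mortality and biomass loss.
#' Shoot density takes the four population states high, moderate, low, zero;
#' "zero" is near-absorbing but recoverable via seed recruitment. CPT values
#' are package fixtures chosen under monotonicity constraints (heat stress
#' never decreases the probability of the zero state in any parent context;
#' sub-optimal temperature never increases the probability of good
#' physiological status), not published field estimates.
#'
#' @return A validated `dbn_spec` with evidence nodes `temperature` and
#'   `heat_stress` and interface nodes `physiological_status` and
#'   `shoot_density`.
#' @export
default_seagrass_dbn <- function() {
  mort_sd <- c(0.00, 0.01, 0.09, 0.90)  # mortality target under heat stress
  base <- .sd_base_rows()
  # rows: first parent varies fastest. Parent order for shoot_density:
  # vegetative_growth, seed_recruitment (same-slice), shoot_density_prev,
  # heat_stress last so the monotone pairing is explicit.
  sd_parents <- c("vegetative_growth", "seed_recruitment", "heat_stress")
  sd_grid <- expand.grid(growth = c("high", "low"), seed = c("yes", "no"),
                         hs = c("none", "present"),
                         prev = c("high", "moderate", "low", "zero"),
                         stringsAsFactors = FALSE)
  # CPT row order must follow parent declaration order:
  # (vegetative_growth, seed_recruitment, heat_stress, shoot_density_prev),
  # first varying fastest — which is exactly sd_grid's column order above
  # reordered: growth, seed, hs, prev.
  sd_cpt <- t(apply(sd_grid, 1, function(r) {
    s <- (r[["growth"]] == "high") + (r[["seed"]] == "yes")
    row <- base[[r[["prev"]]]][s + 1, ]
    if (r[["hs"]] == "present") row <- 0.2 * row + 0.8 * mort_sd
    row
  }))

  bio_grid <- expand.grid(sd = c("high", "moderate", "low", "zero"),
                          hs = c("none", "present"), stringsAsFactors = FALSE)
  bio_base <- rbind(c(0.85, 0.12, 0.025, 0.005),
                    c(0.15, 0.65, 0.17, 0.03),
                    c(0.02, 0.18, 0.60, 0.20),
                    c(0.001, 0.009, 0.14, 0.85))
  rownames(bio_base) <- c("high", "moderate", "low", "zero")
  mort_bio <- c(0.00, 0.01, 0.09, 0.90)
  bio_cpt <- t(apply(bio_grid, 1, function(r) {
    row <- bio_base[r[["sd"]], ]
    if (r[["hs"]] == "present") row <- 0.3 * row + 0.7 * mort_bio
    row
  }))

  seed_grid <- expand.grid(temp = c("optimal", "suboptimal"),
                           prev = c("high", "moderate", "low", "zero"),
                           stringsAsFactors = FALSE)
  seed_yes <- c(high.optimal = 0.80, moderate.optimal = 0.70,
                low.optimal = 0.50, zero.optimal = 0.10,
                high.suboptimal = 0.50, moderate.suboptimal = 0.40,
                low.suboptimal = 0.25, zero.suboptimal = 0.03)
  seed_cpt <- t(apply(seed_grid, 1, function(r) {
    p <- seed_yes[paste(r[["prev"]], r[["temp"]], sep = ".")]
    c(p, 1 - p)
  }))

  nodes <- list(
    dbn_node("temperature", c("optimal", "suboptimal"),
             cpt = rbind(c(0.9, 0.1))),
    dbn_node("heat_stress", c("none", "present"),
             cpt = rbind(c(0.99, 0.01))),
    dbn_node("physiological_status", c("good", "poor"),
             parents = "temperature",
             temporal_parents = "physiological_status",
             # rows: (temperature, physiological_status_prev), first fastest
             cpt = rbind(c(0.95, 0.05),   # optimal, good
                         c(0.60, 0.40),   # suboptimal, good
                         c(0.60, 0.40),   # optimal, poor
                         c(0.15, 0.85))), # suboptimal, poor
    dbn_node("seed_recruitment", c("yes", "no"),
             parents = "temperature",
             temporal_parents = "shoot_density",
             cpt = seed_cpt),
    dbn_node("vegetative_growth", c("high", "low"),
             parents = "physiological_status",
             cpt = rbind(c(0.85, 0.15),   # good
                         c(0.20, 0.80))), # poor
    dbn_node("shoot_density", c("high", "moderate", "low", "zero"),
             parents = sd_parents,
             temporal_parents = "shoot_density",
             cpt = sd_cpt),
    dbn_node("biomass", c("high", "moderate", "low", "zero"),
             parents = c("shoot_density", "heat_stress"),
             cpt = bio_cpt)
  )
  dbn_spec(nodes, evidence_nodes = c("temperature", "heat_stress"))
}
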