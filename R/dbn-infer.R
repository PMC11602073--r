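# -- compiled representation -------------------------------------------------
#
# Exact filtering over the interface joint: for every combination of evidence
# states e we precompute
#   M[[e]]        : |iface| x |iface| transition of the interface joint,
#   G[[e]][[nd]]  : |iface| x |states(nd)| per-node observation matrices,
# by enumerating the free (non-evidence) slice nodes once. Evidence nodes are
# parentless roots, so conditioning on them just selects CPT columns of their
# children and never requires renormalisation (rows of M sum to 1 exactly).

#' Compile a DBN for repeated exact inference
#'
#' Precomputes per-evidence-combination interface transition and observation
#' matrices used by [forward_infer()]. Compiling once and passing the result
#' to repeated inference calls avoids redundant work in Monte Carlo loops.
#'
#' @param dbn A [dbn_spec()].
#' @return An object of class `compiled_dbn`.
#' @export
compile_dbn <- function(dbn) {
  stopifnot(inherits(dbn, "dbn_spec"))
  iface <- dbn$interface_nodes
  ev <- dbn$evidence_nodes
  free <- setdiff(dbn$topo_order, ev)

  iface_grid <- expand.grid(lapply(iface, function(n) dbn$nodes[[n]]$states),
                            stringsAsFactors = FALSE)
  names(iface_grid) <- iface
  ev_grid <- expand.grid(lapply(ev, function(n) dbn$nodes[[n]]$states),
                         stringsAsFactors = FALSE)
  names(ev_grid) <- ev
  free_grid <- expand.grid(lapply(free, function(n) dbn$nodes[[n]]$states),
                           stringsAsFactors = FALSE)
  names(free_grid) <- free

  n_iface <- max(1L, nrow(iface_grid))
  n_ev <- max(1L, nrow(ev_grid))
  n_free <- nrow(free_grid)

  # map each free-grid row to the interface-state index it implies
  iface_cards <- node_cards(dbn, iface)
  iface_idx_of_free <- if (length(iface)) {
    idx <- vapply(iface, function(n) {
      match(free_grid[[n]], dbn$nodes[[n]]$states)
    }, integer(n_free))
    cpt_row_index(iface_cards, matrix(idx, ncol = length(iface)))
  } else rep(1L, n_free)

  M <- vector("list", n_ev)
  G <- vector("list", n_ev)
  for (e in seq_len(n_ev)) {
    Me <- matrix(0, n_iface, n_iface)
    Ge <- lapply(free, function(n) {
      matrix(0, n_iface, length(dbn$nodes[[n]]$states))
    })
    names(Ge) <- free
    for (r in seq_len(n_iface)) {
      # probability of each free-grid row given prev interface r, evidence e
      p <- rep(1, n_free)
      for (nd_name in free) {
        nd <- dbn$nodes[[nd_name]]
        pnames <- c(nd$parents, nd$temporal_parents)
        if (length(pnames)) {
          cards <- node_cards(dbn, pnames)
          idx <- vapply(seq_along(pnames), function(j) {
            pn <- pnames[j]
            temporal <- j > length(nd$parents)
            if (temporal) {
              rep(match(iface_grid[[pn]][r], dbn$nodes[[pn]]$states), n_free)
            } else if (pn %in% ev) {
              rep(match(ev_grid[[pn]][e], dbn$nodes[[pn]]$states), n_free)
            } else {
              match(free_grid[[pn]], dbn$nodes[[pn]]$states)
            }
          }, integer(n_free))
          rows <- cpt_row_index(cards, matrix(idx, ncol = length(pnames)))
        } else {
          rows <- rep(1L, n_free)
        }
        st <- match(free_grid[[nd_name]], nd$states)
        p <- p * nd$cpt[cbind(rows, st)]
      }
      Me[r, ] <- as.numeric(rowsum(p, iface_idx_of_free,
                                   reorder = TRUE))[seq_len(n_iface)]
      for (nd_name in free) {
        st <- match(free_grid[[nd_name]], dbn$nodes[[nd_name]]$states)
        Ge[[nd_name]][r, ] <- as.numeric(rowsum(p, st, reorder = TRUE))
      }
    }
    M[[e]] <- Me
    G[[e]] <- Ge
  }

  structure(list(dbn = dbn, iface = iface, iface_grid = iface_grid,
                 iface_cards = iface_cards, ev = ev, ev_grid = ev_grid,
                 free = free, M = M, G = G),
            class = "compiled_dbn")
}

# Resolve an initial distribution over the interface joint.
# NULL -> uniform; numeric vector of full joint; named list of per-node
# distributions -> independent product.
resolve_initial <- function(cd, initial) {
  n <- max(1L, nrow(cd$iface_grid))
  if (is.null(initial)) return(rep(1 / n, n))
  if (is.numeric(initial) && length(initial) == n) {
    if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
      stop("initial interface distribution is not normalized", call. = FALSE)
    }
    return(as.numeric(initial))
  }
  if (is.list(initial)) {
    f <- rep(1, n)
    for (nd in cd$iface) {
      pr <- initial[[nd]]
      if (is.null(pr)) {
        pr <- rep(1 / length(cd$dbn$nodes[[nd]]$states),
                  length(cd$dbn$nodes[[nd]]$states))
      }
      if (abs(sum(pr) - 1) > 1e-9) {
        stop(sprintf("initial distribution for '%s' is not normalized", nd),
             call. = FALSE)
      }
      st <- match(cd$iface_grid[[nd]], cd$dbn$nodes[[nd]]$states)
      f <- f * pr[st]
    }
    return(f)
  }
  stop("cannot interpret 'initial'", call. = FALSE)
}

# Per-slice evidence -> weights over evidence combinations.
# ev_slice: named list mapping evidence node -> state name (hard) or numeric
# probability vector over its states (soft). Missing nodes use CPT priors.
evidence_weights <- function(cd, ev_slice) {
  n_ev <- max(1L, nrow(cd$ev_grid))
  w <- rep(1, n_ev)
  for (nd in cd$ev) {
    states <- cd$dbn$nodes[[nd]]$states
    v <- ev_slice[[nd]]
    pr <- if (is.null(v)) {
      as.numeric(cd$dbn$nodes[[nd]]$cpt[1, ])
    } else if (is.character(v)) {
      pos <- match(v, states)
      if (is.na(pos)) {
        stop(sprintf("unknown state '%s' for evidence node '%s'", v, nd),
             call. = FALSE)
      }
      as.numeric(seq_along(states) == pos)
    } else {
      if (length(v) != length(states) || abs(sum(v) - 1) > 1e-9) {
        stop(sprintf("soft evidence for '%s' must be a distribution over %s",
                     nd, paste(states, collapse = "/")), call. = FALSE)
      }
      as.numeric(v)
    }
    w <- w * pr[match(cd$ev_grid[[nd]], states)]
  }
  w
}

# Normalise the various evidence inputs to a list of per-slice named lists.
as_evidence_list <- function(cd, evidence) {
  if (is.data.frame(evidence)) {
    cols <- intersect(cd$ev, names(evidence))
    missing_cols <- setdiff(cd$ev, names(evidence))
    if (length(missing_cols)) {
      stop(sprintf("evidence is missing column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    lapply(seq_len(nrow(evidence)), function(i) {
      stats::setNames(lapply(cols, function(cn) evidence[[cn]][i]), cols)
    })
  } else if (is.list(evidence)) {
    evidence
  } else {
    stop("evidence must be a data.frame or a list of per-slice lists",
         call. = FALSE)
  }
}

#' Exact forward inference over a monthly DBN
#'
#' Propagates the joint distribution of the interface nodes slice by slice and
#' returns exact marginal probabilities of every node state at every slice
#' given the evidence up to that slice. Evidence may be hard (state names, as
#' produced by [sample_evidence()]) or soft (per-node probability vectors),
#' and because evidence nodes are parentless roots the filtered marginals
#' equal the fully conditioned ones.
#'
#' @param dbn A [dbn_spec()] or a [compile_dbn()] result.
#' @param evidence Data.frame with one row per slice and one column per
#'   evidence node (hard states), or a list of per-slice named lists whose
#'   elements are state names or probability vectors.
#' @param initial Initial distribution over the interface joint: `NULL`
#'   (uniform), a numeric vector over rows of the interface grid, or a named
#'   list of per-node distributions (independent product).
#' @param keep_nodes Restrict the returned marginals to these nodes (default
#'   all).
#' @return Object of class `state_trajectory`: a long data.frame with columns
#'   `slice`, `node`, `state`, `probability` (plus `year`/`month` when present
#'   in `evidence`). The per-slice interface joints are attached as attribute
#'   `"interface_joint"` (slices x interface-states matrix) and the interface
#'   grid as `"interface_grid"`.
#' @export
forward_infer <- function(dbn, evidence, initial = NULL, keep_nodes = NULL) {
  cd <- if (inherits(dbn, "compiled_dbn")) dbn else compile_dbn(dbn)
  ev_list <- as_evidence_list(cd, evidence)
  n_t <- length(ev_list)
  if (!n_t) stop("no evidence slices", call. = FALSE)
  f <- resolve_initial(cd, initial)
  nodes_out <- if (is.null(keep_nodes)) c(cd$free, cd$ev) else keep_nodes
  unknown <- setdiff(nodes_out, names(cd$dbn$nodes))
  if (length(unknown)) {
    stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  marg <- lapply(nodes_out, function(nd) {
    matrix(NA_real_, n_t, length(cd$dbn$nodes[[nd]]$states))
  })
  names(marg) <- nodes_out
  iface_joint <- matrix(NA_real_, n_t, length(f))

  free_out <- intersect(nodes_out, cd$free)
  ev_out <- intersect(nodes_out, cd$ev)
  for (t in seq_len(n_t)) {
    w <- evidence_weights(cd, ev_list[[t]])
    active <- which(w > 0)
    for (nd in free_out) {
      acc <- 0
      for (e in active) acc <- acc + w[e] * (f %*% cd$G[[e]][[nd]])
      marg[[nd]][t, ] <- acc
    }
    for (nd in ev_out) {
      states <- cd$dbn$nodes[[nd]]$states
      pr <- numeric(length(states))
      for (e in active) {
        pr[match(cd$ev_grid[[nd]][e], states)] <-
          pr[match(cd$ev_grid[[nd]][e], states)] + w[e]
      }
      marg[[nd]][t, ] <- pr
    }
    fn <- 0
    for (e in active) fn <- fn + w[e] * (f %*% cd$M[[e]])
    f <- as.numeric(fn)
    iface_joint[t, ] <- f
  }

  meta <- NULL
  if (is.data.frame(evidence)) {
    keep <- intersect(c("year", "month"), names(evidence))
    if (length(keep)) meta <- evidence[, keep, drop = FALSE]
  }
  out <- do.call(rbind, lapply(nodes_out, function(nd) {
    states <- cd$dbn$nodes[[nd]]$states
    df <- data.frame(
      slice = rep(seq_len(n_t), times = length(states)),
      node = nd,
      state = rep(states, each = n_t),
      probability = as.numeric(marg[[nd]])
    )
    df
  }))
  if (!is.null(meta)) {
    out <- cbind(out, meta[out$slice, , drop = FALSE])
    rownames(out) <- NULL
  }
  structure(out, class = c("state_trajectory", "data.frame"),
            interface_joint = iface_joint,
            interface_grid = cd$iface_grid)
}

#' @export
print.state_trajectory <- function(x, ...) {
  if (!is.null(x$slice) && !is.null(x$node)) {
    cat(sprintf("State trajectory: %d slice(s), %d node(s)\n",
                max(x$slice), length(unique(x$node))))
  }
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("  ... %d more rows\n", nrow(x) - 8))
  invisible(x)
}

#' Brute-force joint enumeration (test oracle)
#'
#' Computes node-state marginals by summing the full joint distribution over
#' every assignment of every unobserved variable across all slices,
#' conditioning on the evidence. Independent of the interface-filtering code
#' path; intended as an oracle for small networks.
#'
#' @inheritParams forward_infer
#' @param cap Refuse when the total number of joint assignments exceeds this.
#' @return A `state_trajectory` data.frame (no interface attributes).
#' @export
enumerate_joint <- function(dbn, evidence, initial = NULL, cap = 1e7) {
  stopifnot(inherits(dbn, "dbn_spec"))
  ev_nodes <- dbn$evidence_nodes
  iface <- dbn$interface_nodes
  free <- setdiff(dbn$topo_order, ev_nodes)
  if (is.data.frame(evidence)) {
    ev_list <- lapply(seq_len(nrow(evidence)), function(i) {
      stats::setNames(lapply(ev_nodes, function(cn) evidence[[cn]][i]),
                      ev_nodes)
    })
  } else ev_list <- evidence
  n_t <- length(ev_list)

  # variables: interface nodes at slice 0, then free nodes at slices 1..T;
  # evidence nodes with hard values are fixed, soft/missing ones enumerated.
  vars <- list()
  for (nd in iface) {
    vars[[paste0(nd, "@0")]] <- dbn$nodes[[nd]]$states
  }
  hard <- vector("list", n_t)
  soft <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    hard[[t]] <- list(); soft[[t]] <- list()
    for (nd in ev_nodes) {
      v <- ev_list[[t]][[nd]]
      if (is.character(v)) {
        hard[[t]][[nd]] <- v
      } else {
        pr <- if (is.null(v)) as.numeric(dbn$nodes[[nd]]$cpt[1, ]) else v
        soft[[t]][[nd]] <- pr
        vars[[paste0(nd, "@", t)]] <- dbn$nodes[[nd]]$states
      }
    }
    for (nd in free) {
      vars[[paste0(nd, "@", t)]] <- dbn$nodes[[nd]]$states
    }
  }
  size <- prod(vapply(vars, length, integer(1)))
  if (size > cap) {
    stop(sprintf("joint outcome space has %.3g assignments, exceeding cap %.3g",
                 size, cap), call. = FALSE)
  }
  grid <- expand.grid(vars, stringsAsFactors = FALSE)

  value_of <- function(nd, t, r = NULL) {
    key <- paste0(nd, "@", t)
    if (!is.null(grid[[key]])) return(grid[[key]])
    rep(hard[[t]][[nd]], nrow(grid))
  }

  p <- rep(1, nrow(grid))
  # slice-0 interface prior
  if (length(iface)) {
    cd0 <- list(dbn = dbn, iface = iface,
                iface_grid = stats::setNames(
                  expand.grid(lapply(iface, function(n) dbn$nodes[[n]]$states),
                              stringsAsFactors = FALSE), iface))
    f0 <- resolve_initial(cd0, initial)
    idx <- vapply(iface, function(nd) {
      match(grid[[paste0(nd, "@0")]], dbn$nodes[[nd]]$states)
    }, integer(nrow(grid)))
    row0 <- cpt_row_index(node_cards(dbn, iface),
                          matrix(idx, ncol = length(iface)))
    p <- p * f0[row0]
  }
  for (t in seq_len(n_t)) {
    for (nd_name in dbn$topo_order) {
      nd <- dbn$nodes[[nd_name]]
      if (nd_name %in% ev_nodes) {
        if (!is.null(hard[[t]][[nd_name]])) next  # conditioned on
        pr <- soft[[t]][[nd_name]]
        st <- match(grid[[paste0(nd_name, "@", t)]], nd$states)
        p <- p * pr[st]
        next
      }
      pnames <- c(nd$parents, nd$temporal_parents)
      if (length(pnames)) {
        cards <- node_cards(dbn, pnames)
        idx <- vapply(seq_along(pnames), function(j) {
          pn <- pnames[j]
          pt <- if (j > length(nd$parents)) t - 1L else t
          match(value_of(pn, pt), dbn$nodes[[pn]]$states)
        }, integer(nrow(grid)))
        rows <- cpt_row_index(cards, matrix(idx, ncol = length(pnames)))
      } else {
        rows <- rep(1L, nrow(grid))
      }
      st <- match(grid[[paste0(nd_name, "@", t)]], nd$states)
      p <- p * nd$cpt[cbind(rows, st)]
    }
  }
  z <- sum(p)

  out <- list()
  for (t in seq_len(n_t)) {
    for (nd_name in dbn$topo_order) {
      states <- dbn$nodes[[nd_name]]$states
      key <- paste0(nd_name, "@", t)
      pr <- if (!is.null(grid[[key]])) {
        v <- rowsum(p, match(grid[[key]], states), reorder = TRUE)
        full <- numeric(length(states))
        full[as.integer(rownames(v))] <- v
        full / z
      } else {
        as.numeric(states == hard[[t]][[nd_name]])
      }
      out[[length(out) + 1L]] <- data.frame(
        slice = t, node = nd_name, state = states, probability = pr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("state_trajectory", "data.frame"))
}

#' Sample a monthly evidence sequence from climate probabilities
#'
#' For each month, the temperature node is sub-optimal with probability
#' `p_suboptimal` and the heat-stress node is present with probability
#' `p_heatstress`, drawn independently (the study's sampling scheme). An
#' optional physical-coupling rule forces sub-optimal temperature whenever
#' heat stress is sampled present.
#'
#' @param probs Data.frame from [project_monthly_probabilities()] (columns
#'   `year`, `month`, `p_suboptimal`, `p_heatstress`).
#' @param seed Integer seed.
#' @param couple_heat_to_temp Force temperature sub-optimal in heat-stress
#'   months (off by default).
#' @param nodes Names of the two evidence nodes.
#' @param states Named list giving the (no, yes) state pair of each node.
#' @return Data.frame `year`, `month`, `temperature`, `heat_stress` with state
#'   labels, suitable as hard evidence for [forward_infer()].
#' @export
sample_evidence <- function(probs, seed, couple_heat_to_temp = FALSE,
                            nodes = c("temperature", "heat_stress"),
                            states = list(temperature = c("optimal", "suboptimal"),
                                          heat_stress = c("none", "present"))) {
  need <- c("p_suboptimal", "p_heatstress")
  if (!all(need %in% names(probs))) {
    stop("probs must carry p_suboptimal and p_heatstress", call. = FALSE)
  }
  if (anyNA(probs$p_suboptimal) || anyNA(probs$p_heatstress)) {
    stop("month without probabilities", call. = FALSE)
  }
  n <- nrow(probs)
  draws <- with_private_seed(seed, stats::runif(2 * n))
  sub <- draws[seq_len(n)] < probs$p_suboptimal
  hs <- draws[n + seq_len(n)] < probs$p_heatstress
  if (couple_heat_to_temp) sub <- sub | hs
  out <- data.frame(
    year = if ("year" %in% names(probs)) probs$year else NA_integer_,
    month = if ("month" %in% names(probs)) probs$month else seq_len(n)
  )
  out[[nodes[1]]] <- states[[nodes[1]]][sub + 1L]
  out[[nodes[2]]] <- states[[nodes[2]]][hs + 1L]
  out
}
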