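#' Decision-tree nodes
#'
#' Constructors for the three node kinds of a rooted decision tree:
#' terminal nodes carry a monetary payoff (EUR, may be negative), chance
#' nodes carry probability-weighted branches, and decision nodes carry
#' unweighted branches among which the decision maker chooses.
#'
#' Because nodes are plain R lists, a tree is always finite and acyclic by
#' construction. Chance-branch probabilities must lie in \[0, 1\] and sum to
#' 1; sums deviating from 1 by at most `1e-6` are tolerated and renormalized
#' (with a warning) when the tree is evaluated, which accommodates published
#' parameter tables whose printed probabilities carry rounding error.
#'
#' @param label Short text naming the node.
#' @param payoff Terminal payoff in EUR.
#' @param branches List of branches built with [dt_branch()].
#' @param child Child node of a branch.
#' @param p Branch probability (chance branches only; omit for decision
#'   branches).
#' @return A `dtree_node` object, or for `dt_branch` a branch list used
#'   inside a node.
#' @examples
#' tree <- dt_chance("calf sex", list(
#'   dt_branch("male", dt_terminal("male calf", 50), p = 0.485),
#'   dt_branch("female", dt_terminal("female calf", 100), p = 0.515)
#' ))
#' rollback(tree)$root_emv
#' @seealso [rollback()], [enumerate_paths()], [validate_tree()]
#' @export
dt_terminal <- function(label, payoff) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(payoff) || length(payoff) != 1L || !is.finite(payoff)) {
    stop("terminal payoff must be a single finite number", call. = FALSE)
  }
  structure(
    list(kind = "terminal", label = label, payoff = as.numeric(payoff),
         branches = list()),
    class = "dtree_node"
  )
}

#' @rdname dt_terminal
#' @export
dt_chance <- function(label, branches) {
  stopifnot(is.character(label), length(label) == 1L, is.list(branches))
  structure(
    list(kind = "chance", label = label, payoff = NULL, branches = branches),
    class = "dtree_node"
  )
}

#' @rdname dt_terminal
#' @export
dt_decision <- function(label, branches) {
  stopifnot(is.character(label), length(label) == 1L, is.list(branches))
  structure(
    list(kind = "decision", label = label, payoff = NULL,
         branches = branches),
    class = "dtree_node"
  )
}

#' @rdname dt_terminal
#' @export
dt_branch <- function(label, child, p = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  list(label = label, p = if (!is.null(p)) as.numeric(p), child = child)
}

#' @export
print.dtree_node <- function(x, ...) {
  cat(format_dtree(x), sep = "\n")
  invisible(x)
}

format_dtree <- function(node, prefix = "", branch_txt = NULL) {
  head <- switch(node$kind,
    terminal = sprintf("<terminal> %s : EUR %.2f", node$label, node$payoff),
    chance   = sprintf("(chance) %s", node$label),
    decision = sprintf("[decision] %s", node$label),
    sprintf("<?%s?> %s", node$kind, node$label)
  )
  if (!is.null(branch_txt)) head <- paste0(branch_txt, " ", head)
  out <- paste0(prefix, head)
  for (b in node$branches) {
    btxt <- if (is.null(b$p)) sprintf("-- %s -->", b$label) else
      sprintf("-- %s (p=%g) -->", b$label, b$p)
    out <- c(out, format_dtree(b$child, paste0(prefix, "  "), btxt))
  }
  out
}

# Walk the tree depth-first assigning positional ids ("0", "0.1", "0.2.1"...)
# and calling fn(node, id) at each node. Branch order is declaration order.
walk_tree <- function(node, fn, id = "0") {
  fn(node, id)
  bs <- node$branches
  if (length(bs)) {
    for (i in seq_along(bs)) {
      walk_tree(bs[[i]]$child, fn, paste0(id, ".", i))
    }
  }
  invisible(NULL)
}

#' Validate a decision tree
#'
#' Checks every structural invariant of a [dt_terminal()]/[dt_chance()]/
#' [dt_decision()] tree and returns diagnostics rather than throwing: an
#' empty character vector means the tree is valid. Each diagnostic names the
#' offending node (by its positional id and label) and the violated rule.
#'
#' Rules: terminal nodes have a finite payoff and no branches; chance nodes
#' have at least one branch, every probability in \[0, 1\], and probabilities
#' summing to 1 within `1e-6` (small deviations are later renormalized by
#' the evaluators); decision nodes have at least one branch and no branch
#' probabilities.
#'
#' @param tree A `dtree_node`.
#' @return Character vector of diagnostics; `character(0)` if valid.
#' @examples
#' validate_tree(dt_terminal("ok", 42))       # character(0)
#' bad <- dt_chance("x", list(
#'   dt_branch("a", dt_terminal("t", 1), p = 0.6),
#'   dt_branch("b", dt_terminal("t", 2), p = 0.6)
#' ))
#' validate_tree(bad)
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "dtree_node")) {
    return("root: not a dtree_node object")
  }
  diags <- character(0)
  add <- function(id, node, msg) {
    diags <<- c(diags, sprintf("node %s (%s): %s", id, node$label, msg))
  }
  walk <- function(node, id, depth) {
    if (depth > 10000L) stop("tree deeper than 10000 levels", call. = FALSE)
    if (!inherits(node, "dtree_node") || !node$kind %in%
          c("terminal", "chance", "decision")) {
      diags <<- c(diags, sprintf("node %s: unknown node kind", id))
      return(invisible(NULL))
    }
    nb <- length(node$branches)
    if (node$kind == "terminal") {
      if (nb > 0L) add(id, node, "terminal node has branches")
      if (!is.numeric(node$payoff) || length(node$payoff) != 1L ||
            !is.finite(node$payoff)) {
        add(id, node, "terminal node lacks a finite payoff")
      }
    } else {
      if (nb < 1L) add(id, node, "non-terminal node has no branches")
      if (!is.null(node$payoff)) add(id, node, "non-terminal node has a payoff")
      ps <- vapply(node$branches, function(b) {
        if (is.null(b$p)) NA_real_ else b$p
      }, numeric(1))
      if (node$kind == "chance") {
        if (anyNA(ps)) {
          add(id, node, "chance branch lacks a probability")
        } else {
          if (any(ps < 0 | ps > 1)) add(id, node, "probability out of range")
          if (abs(sum(ps) - 1) > 1e-6) {
            add(id, node, sprintf("probabilities sum != 1 (sum = %.9g)",
                                  sum(ps)))
          }
        }
      } else {                          # decision
        if (!all(is.na(ps))) {
          add(id, node, "decision branches must not carry probabilities")
        }
      }
    }
    if (nb > 0L) {
      for (i in seq_len(nb)) {
        walk(node$branches[[i]]$child, paste0(id, ".", i), depth + 1L)
      }
    }
    invisible(NULL)
  }
  walk(tree, "0", 1L)
  diags
}

stop_if_invalid <- function(tree) {
  d <- validate_tree(tree)
  if (length(d)) {
    stop("invalid decision tree:\n  ", paste(d, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(tree)
}

# Renormalize chance probabilities whose sum deviates from 1 by <= 1e-6
# (validate_tree has already rejected larger deviations). Warns once,
# naming the affected nodes.
renormalize_tree <- function(tree) {
  touched <- character(0)
  fix <- function(node, id) {
    if (node$kind == "chance") {
      ps <- vapply(node$branches, `[[`, numeric(1), "p")
      s <- sum(ps)
      if (abs(s - 1) > 1e-9) {
        for (i in seq_along(node$branches)) {
          node$branches[[i]]$p <- ps[i] / s
        }
        touched <<- c(touched, sprintf("%s (%s)", id, node$label))
      }
    }
    if (length(node$branches)) {
      for (i in seq_along(node$branches)) {
        node$branches[[i]]$child <- fix(node$branches[[i]]$child,
                                        paste0(id, ".", i))
      }
    }
    node
  }
  out <- fix(tree, "0")
  if (length(touched)) {
    warning("renormalized chance probabilities at: ",
            paste(touched, collapse = ", "), call. = FALSE)
  }
  out
}

#' Expected-monetary-value rollback of a decision tree
#'
#' Backward induction: terminal nodes evaluate to their payoff, chance nodes
#' to the probability-weighted mean of their children, decision nodes to the
#' maximum over their children (risk-neutral expected monetary value). Ties
#' at a decision node break deterministically in favour of the first branch
#' in declaration order. Chance probabilities whose sum deviates from 1 by
#' at most `1e-6` are renormalized with a warning before evaluation.
#'
#' @param tree A valid `dtree_node` (see [validate_tree()]).
#' @param policy Optional named character vector fixing the branch taken at
#'   each decision node (names are positional node ids as reported by
#'   [decision_nodes()]). When supplied, decision nodes follow the policy
#'   instead of maximizing.
#' @return A `dtree_rollback` object: list with `root_emv`, `emv_by_node`
#'   (named numeric, positional ids), `optimal_choice` (named character,
#'   one entry per decision node) and `tree` (the renormalized tree).
#' @examples
#' tree <- dt_decision("monitor?", list(
#'   dt_branch("yes", dt_terminal("a", 20)),
#'   dt_branch("no", dt_terminal("b", 15))
#' ))
#' r <- rollback(tree)
#' r$root_emv          # 20
#' r$optimal_choice    # "yes"
#' @export
rollback <- function(tree, policy = NULL) {
  stop_if_invalid(tree)
  tree <- renormalize_tree(tree)
  emv <- numeric(0)
  choice <- character(0)
  eval_node <- function(node, id) {
    v <- switch(node$kind,
      terminal = node$payoff,
      chance = {
        vs <- vapply(seq_along(node$branches), function(i) {
          eval_node(node$branches[[i]]$child, paste0(id, ".", i))
        }, numeric(1))
        ps <- vapply(node$branches, `[[`, numeric(1), "p")
        sum(ps * vs)
      },
      decision = {
        vs <- vapply(seq_along(node$branches), function(i) {
          eval_node(node$branches[[i]]$child, paste0(id, ".", i))
        }, numeric(1))
        labs <- vapply(node$branches, `[[`, character(1), "label")
        if (!is.null(policy)) {
          if (!id %in% names(policy)) {
            stop("policy missing decision node ", id, " (", node$label, ")",
                 call. = FALSE)
          }
          j <- match(policy[[id]], labs)
          if (is.na(j)) {
            stop("policy names unknown branch '", policy[[id]],
                 "' at node ", id, call. = FALSE)
          }
        } else {
          j <- which.max(vs)            # first maximum wins ties
        }
        choice[id] <<- labs[j]
        vs[j]
      }
    )
    emv[id] <<- v
    v
  }
  root <- eval_node(tree, "0")
  structure(
    list(root_emv = root, emv_by_node = emv, optimal_choice = choice,
         policy = policy, tree = tree),
    class = "dtree_rollback"
  )
}

#' @export
print.dtree_rollback <- function(x, ...) {
  cat(sprintf("Decision-tree rollback: root EMV = EUR %.2f\n", x$root_emv))
  if (length(x$optimal_choice)) {
    cat(if (is.null(x$policy)) "Optimal choices:\n" else "Policy followed:\n")
    for (id in names(x$optimal_choice)) {
      cat(sprintf("  %s -> %s\n", id, x$optimal_choice[[id]]))
    }
  }
  invisible(x)
}

#' List the decision nodes of a tree
#'
#' @param tree A `dtree_node`.
#' @return Data frame with columns `id` (positional node id), `label`, and
#'   `branches` (comma-separated branch labels).
#' @export
decision_nodes <- function(tree) {
  ids <- character(0); labs <- character(0); brs <- character(0)
  walk_tree(tree, function(node, id) {
    if (node$kind == "decision") {
      ids <<- c(ids, id)
      labs <<- c(labs, node$label)
      brs <<- c(brs, paste(vapply(node$branches, `[[`, character(1), "label"),
                           collapse = ","))
    }
  })
  data.frame(id = ids, label = labs, branches = brs,
             stringsAsFactors = FALSE)
}

#' Enumerate all root-to-terminal paths of a decision tree
#'
#' Exhaustive path enumeration under a fixed decision policy. This is the
#' brute-force counterpart of [rollback()]: the probability-weighted sum of
#' path payoffs equals the rollback EMV of the same policy, and path
#' probabilities sum to 1 — both useful as independent cross-checks.
#'
#' @param tree A valid `dtree_node`.
#' @param policy Named character vector (positional decision-node id ->
#'   branch label). Required if the tree contains decision nodes.
#' @return A `dtree_paths` data frame with columns `path` (branch labels
#'   joined by " / "), `probability` and `payoff`.
#' @examples
#' tree <- dt_chance("toss", list(
#'   dt_branch("lose", dt_terminal("t0", 0), p = 0.3),
#'   dt_branch("win", dt_terminal("t1", 100), p = 0.7)
#' ))
#' pt <- enumerate_paths(tree)
#' sum(pt$probability * pt$payoff)  # 70
#' @export
enumerate_paths <- function(tree, policy = NULL) {
  stop_if_invalid(tree)
  tree <- renormalize_tree(tree)
  paths <- character(0); probs <- numeric(0); pays <- numeric(0)
  rec <- function(node, id, lab, p) {
    if (node$kind == "terminal") {
      paths <<- c(paths, paste(lab, collapse = " / "))
      probs <<- c(probs, p)
      pays <<- c(pays, node$payoff)
      return(invisible(NULL))
    }
    labs <- vapply(node$branches, `[[`, character(1), "label")
    if (node$kind == "chance") {
      for (i in seq_along(node$branches)) {
        rec(node$branches[[i]]$child, paste0(id, ".", i),
            c(lab, labs[i]), p * node$branches[[i]]$p)
      }
    } else {                            # decision: follow the policy
      if (is.null(policy) || !id %in% names(policy)) {
        stop("policy missing decision node ", id, " (", node$label, ")",
             call. = FALSE)
      }
      j <- match(policy[[id]], labs)
      if (is.na(j)) {
        stop("policy names unknown branch '", policy[[id]], "' at node ", id,
             call. = FALSE)
      }
      rec(node$branches[[j]]$child, paste0(id, ".", j), c(lab, labs[j]), p)
    }
  }
  rec(tree, "0", character(0), 1)
  out <- data.frame(path = paths, probability = probs, payoff = pays,
                    stringsAsFactors = FALSE)
  if (!nrow(out)) out <- data.frame(path = "", probability = 1,
                                    payoff = tree$payoff)
  class(out) <- c("dtree_paths", "data.frame")
  out
}

#' Enumerate every decision policy of a tree
#'
#' Cartesian product of branch choices over all decision nodes; used for
#' exhaustive policy search when verifying that [rollback()] selects the
#' EMV-maximizing policy.
#'
#' @param tree A valid `dtree_node`.
#' @param max_policies Safety cap on the number of policies.
#' @return List of named character vectors, each a complete policy.
#' @export
enumerate_policies <- function(tree, max_policies = 1e5) {
  dn <- decision_nodes(tree)
  if (!nrow(dn)) return(list(stats::setNames(character(0), character(0))))
  opts <- strsplit(dn$branches, ",", fixed = TRUE)
  n_pol <- prod(lengths(opts))
  if (n_pol > max_policies) {
    stop("tree has ", n_pol, " policies; raise max_policies to enumerate",
         call. = FALSE)
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  names(grid) <- dn$id
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.character(grid[i, ]), dn$id)
  })
}

#' Policy value via path enumeration
#'
#' Expectation of terminal payoffs under a fixed policy, computed from
#' [enumerate_paths()] — an evaluation route independent of [rollback()].
#'
#' @inheritParams enumerate_paths
#' @return Single numeric EMV in EUR.
#' @export
policy_value <- function(tree, policy = NULL) {
  pt <- enumerate_paths(tree, policy)
  sum(pt$probability * pt$payoff)
}

#' One-way sensitivity sweep of a decision tree
#'
#' Rebuilds a tree over an evenly spaced grid of values of one parameter,
#' spanning `baseline * (1 - relative_range)` to `baseline *
#' (1 + relative_range)` inclusive, and records the rollback root EMV at
#' every grid point. Grid values pushed outside a `clamp` interval (e.g.
#' \[0, 1\] for probabilities) are evaluated at the boundary and flagged;
#' the reported grid keeps the nominal values so it stays strictly
#' increasing.
#'
#' @param builder Function taking a named list of parameters and returning a
#'   `dtree_node`.
#' @param params Named list of baseline parameters passed to `builder`.
#' @param parameter_name Name of the entry in `params` to vary.
#' @param relative_range Relative half-width of the sweep (0.5 means ±50%).
#'   A zero range yields a single-point sweep.
#' @param steps Number of grid points (>= 2 unless `relative_range` is 0).
#' @param clamp Optional length-2 numeric interval to clamp effective
#'   parameter values to (default none).
#' @param response Optional function `(tree, params) -> numeric` replacing
#'   the default response, the rollback root EMV.
#' @return A `sensitivity_sweep` object: list with `parameter_name`, `grid`,
#'   `effective_grid`, `clamped` (logical), `emv_series`, `baseline_value`
#'   and `baseline_emv`.
#' @examples
#' builder <- function(p) dt_terminal("payout", p$value)
#' sw <- one_way_sensitivity(builder, list(value = 100), "value", 0.5, 3)
#' sw$emv_series   # 50 100 150
#' @export
one_way_sensitivity <- function(builder, params, parameter_name,
                                relative_range, steps = 11L,
                                clamp = NULL, response = NULL) {
  if (!parameter_name %in% names(params)) {
    stop("unknown parameter '", parameter_name, "'; valid names: ",
         paste(names(params), collapse = ", "), call. = FALSE)
  }
  stopifnot(relative_range >= 0)
  baseline <- params[[parameter_name]]
  if (relative_range == 0) {
    grid <- baseline
  } else {
    if (steps < 2L) stop("steps must be >= 2", call. = FALSE)
    grid <- seq(baseline * (1 - relative_range),
                baseline * (1 + relative_range), length.out = steps)
  }
  eff <- grid
  clamped <- rep(FALSE, length(grid))
  if (!is.null(clamp)) {
    clamped <- grid < clamp[1] | grid > clamp[2]
    eff <- pmin(pmax(grid, clamp[1]), clamp[2])
  }
  if (is.null(response)) {
    response <- function(tree, params) rollback(tree)$root_emv
  }
  series <- vapply(eff, function(v) {
    p <- params
    p[[parameter_name]] <- v
    response(builder(p), p)
  }, numeric(1))
  base_p <- params
  structure(
    list(parameter_name = parameter_name, grid = grid,
         effective_grid = eff, clamped = clamped, emv_series = series,
         baseline_value = baseline,
         baseline_emv = response(builder(base_p), base_p)),
    class = "sensitivity_sweep"
  )
}

#' @export
print.sensitivity_sweep <- function(x, ...) {
  cat(sprintf("One-way sensitivity sweep on '%s' (baseline %.4g, EMV %.2f)\n",
              x$parameter_name, x$baseline_value, x$baseline_emv))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sensitivity_sweep <- function(x, ...) {
  data.frame(parameter = x$parameter_name, value = x$grid,
             effective_value = x$effective_grid, clamped = x$clamped,
             emv = x$emv_series, stringsAsFactors = FALSE)
}

#' Export a decision tree to Graphviz DOT
#'
#' Decision nodes render as boxes, chance nodes as ellipses, terminal nodes
#' as plain boxes annotated with their payoff; edges carry the branch label
#' and, for chance branches, the probability.
#'
#' @param tree A valid `dtree_node`.
#' @return Single character string with the DOT source.
#' @export
to_dot <- function(tree) {
  stop_if_invalid(tree)
  esc <- function(s) gsub('"', '\\\\"', s)
  nodes <- character(0); edges <- character(0)
  counter <- 0L
  emit <- function(node) {
    me <- sprintf("n%d", counter); counter <<- counter + 1L
    nodes[[length(nodes) + 1L]] <<- switch(node$kind,
      terminal = sprintf('%s [shape=none, label="%s\\nEUR %.2f"];',
                         me, esc(node$label), node$payoff),
      chance   = sprintf('%s [shape=ellipse, label="%s"];',
                         me, esc(node$label)),
      decision = sprintf('%s [shape=box, label="%s"];', me, esc(node$label))
    )
    for (b in node$branches) {
      ch <- emit(b$child)
      lab <- if (is.null(b$p)) esc(b$label) else
        sprintf("%s\\np=%.4g", esc(b$label), b$p)
      edges[[length(edges) + 1L]] <<-
        sprintf('%s -> %s [label="%s"];', me, ch, lab)
    }
    me
  }
  emit(tree)
  paste(c("digraph decision_tree {", "  rankdir=LR;",
          paste0("  ", nodes), paste0("  ", edges), "}"),
        collapse = "\n")
}

#' Serialize a decision tree to JSON and back
#'
#' Node objects are written as `{"kind", "label", "payoff", "branches":
#' [{"label", "p", "child"}]}`. The round trip is stable: a tree read back
#' from its own JSON is identical to the original.
#'
#' @param tree A valid `dtree_node`.
#' @param text JSON text produced by `tree_to_json()`.
#' @return `tree_to_json()`: a JSON string; `tree_from_json()`: a
#'   `dtree_node`.
#' @export
tree_to_json <- function(tree) {
  stop_if_invalid(tree)
  as_plain <- function(node) {
    out <- list(kind = node$kind, label = node$label)
    if (node$kind == "terminal") out$payoff <- node$payoff
    if (length(node$branches)) {
      out$branches <- lapply(node$branches, function(b) {
        bb <- list(label = b$label)
        if (!is.null(b$p)) bb$p <- b$p
        bb$child <- as_plain(b$child)
        bb
      })
    }
    out
  }
  jsonlite::toJSON(as_plain(tree), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(text) {
  build <- function(x) {
    branches <- lapply(x$branches, function(b) {
      dt_branch(b$label, build(b$child), p = b$p)
    })
    switch(x$kind,
      terminal = dt_terminal(x$label, x$payoff),
      chance   = dt_chance(x$label, branches),
      decision = dt_decision(x$label, branches),
      stop("unknown node kind '", x$kind, "' in JSON", call. = FALSE)
    )
  }
  build(jsonlite::fromJSON(text, simplifyVector = FALSE))
}
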