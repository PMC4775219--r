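#' @useDynLib rascycle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A reaction: <=2 reactants, <=2 products, forward/reverse rate constants and
# role tags used by apply_mutant(). Internal constructor; networks are built
# through the build_* functions.
new_reaction <- function(reactants, products, k_fwd, k_rev = 0,
                         role_fwd = NA_character_, role_rev = NA_character_) {
  stopifnot(length(reactants) >= 1, length(reactants) <= 2,
            length(products) >= 1, length(products) <= 2)
  if (k_fwd < 0 || k_rev < 0) stop("rate constants must be non-negative")
  list(reactants = reactants, products = products,
       k_fwd = k_fwd, k_rev = k_rev,
       role_fwd = role_fwd, role_rev = role_rev)
}

new_network <- function(model, species, reactions, k,
                        effectors = character(), ic_defaults = numeric(),
                        routing = list(intrinsic = TRUE, gap = TRUE,
                                       effector = TRUE),
                        exch_rate_fn = NULL, feedback = NULL) {
  structure(list(model = model, species = species, reactions = reactions,
                 k = k, effectors = effectors, ic_defaults = ic_defaults,
                 routing = routing, exch_rate_fn = exch_rate_fn,
                 feedback = feedback),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> model:", x$model, "\n")
  cat("  species  :", paste(x$species, collapse = ", "), "\n")
  cat("  effectors:", if (length(x$effectors))
    paste(x$effectors, collapse = ", ") else "(none)", "\n")
  for (r in x$reactions) {
    arrow <- if (r$k_rev > 0) "<->" else "->"
    cat(sprintf("  %s %s %s   k+ = %g%s\n",
                paste(r$reactants, collapse = " + "), arrow,
                paste(r$products, collapse = " + "), r$k_fwd,
                if (r$k_rev > 0) sprintf(", k- = %g", r$k_rev) else ""))
  }
  if (!is.null(x$exch_rate_fn))
    cat("  exchange rate: state-dependent (", x$feedback$type, " feedback)\n",
        sep = "")
  invisible(x)
}

# species naming helpers ------------------------------------------------

eff_species <- function(name) if (name == "EFF") "EFF" else paste0("EFF_", name)
gt_eff_species <- function(name)
  if (name == "EFF") "GT_EFF" else paste0("GT_EFF_", name)
gt_gef_eff_species <- function(name)
  if (name == "EFF") "GT_GEF_EFF" else paste0("GT_GEF_EFF_", name)

# GTPase-containing species of a network (exactly one must appear on each
# side of every reaction -- checked in validate_network()).
gtpase_species <- function(net) {
  sp <- net$species
  core <- c("G", "GT", "GD", "GI")
  sp[sp %in% core | startsWith(sp, "GT_")]
}

#' Conserved totals of a network state
#'
#' Sums the species participating in each conservation law: total GTPase,
#' total of each effector, total GAP and (for feedback models) total GEF.
#'
#' @param net a `reaction_network`.
#' @param state named concentration vector (nM).
#' @return Named numeric vector of totals.
#' @export
conserved_totals <- function(net, state) {
  state <- state[net$species]
  tot <- c(gtpase = sum(state[gtpase_species(net)]))
  for (e in net$effectors) {
    sp <- intersect(c(eff_species(e), gt_eff_species(e), gt_gef_eff_species(e)),
                    net$species)
    tot[paste0("effector_", e)] <- sum(state[sp])
  }
  if ("GAP" %in% net$species)
    tot["gap"] <- sum(state[c("GAP", "GT_GAP")])
  if ("GEF" %in% net$species)
    tot["gef"] <- sum(state[intersect(
      c("GEF", "GT_GEF", vapply(net$effectors, gt_gef_eff_species, "")),
      net$species)])
  tot
}

validate_network <- function(net) {
  sp <- net$species
  if (anyDuplicated(sp)) stop("duplicate species names")
  gs <- gtpase_species(net)
  for (r in net$reactions) {
    unknown <- setdiff(c(r$reactants, r$products), sp)
    if (length(unknown))
      stop("reaction refers to unknown species: ",
           paste(unknown, collapse = ", "))
    if (sum(r$reactants %in% gs) != 1 || sum(r$products %in% gs) != 1)
      stop("each reaction must carry exactly one GTPase species per side: ",
           paste(r$reactants, collapse = "+"), " -> ",
           paste(r$products, collapse = "+"))
  }
  invisible(net)
}

# Expand reversible reactions into irreversible ones and precompute the
# stoichiometry and rate-evaluation indices used by the ODE right-hand side.
compile_network <- function(net) {
  sp <- net$species
  n <- length(sp)
  i1 <- integer(0); i2 <- integer(0); kv <- numeric(0)
  Scols <- list()
  exch_idx <- integer(0)
  add <- function(reactants, products, k, is_exch) {
    col <- numeric(n)
    for (s in reactants) col[match(s, sp)] <- col[match(s, sp)] - 1
    for (s in products) col[match(s, sp)] <- col[match(s, sp)] + 1
    Scols[[length(Scols) + 1L]] <<- col
    i1 <<- c(i1, match(reactants[1], sp))
    i2 <<- c(i2, if (length(reactants) == 2) match(reactants[2], sp) else 0L)
    kv <<- c(kv, k)
    if (is_exch) exch_idx <<- c(exch_idx, length(kv))
  }
  for (r in net$reactions) {
    if (r$k_fwd > 0 || identical(r$role_fwd, "exch"))
      add(r$reactants, r$products, r$k_fwd, identical(r$role_fwd, "exch"))
    if (r$k_rev > 0)
      add(r$products, r$reactants, r$k_rev, FALSE)
  }
  S <- if (length(Scols)) do.call(cbind, Scols) else matrix(0, n, 0)
  list(S = S, i1 = i1, i2 = i2, k = kv, exch_idx = exch_idx,
       species = sp, exch_rate_fn = net$exch_rate_fn)
}

# ODE right-hand side shared by simulate() and steady_state().
make_derivs <- function(cmp) {
  function(t, x, p) {
    k <- cmp$k
    if (!is.null(cmp$exch_rate_fn) && length(cmp$exch_idx))
      k[cmp$exch_idx] <- cmp$exch_rate_fn(x)
    v <- k * x[cmp$i1] * c(1, x)[cmp$i2 + 1L]
    list(as.vector(cmp$S %*% v))
  }
}
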