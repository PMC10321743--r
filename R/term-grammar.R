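# Symbolic tensor term grammar.
#
# A library term is a (small) linear combination of monomials; a monomial is
# a product of factors; a factor is the velocity u, the director n, a
# Kronecker delta or 2D Levi-Civita symbol, carrying a time-derivative order,
# a multi-index of spatial-derivative labels and component labels.  Free
# tensor indices are labeled "i", "j"; contracted indices use "a".."h", each
# appearing exactly twice in a monomial.  Rank-2 terms are projected onto
# the symmetric-traceless or antisymmetric irreducible class, which is what
# turns single monomials into combinations.

FREE_LABELS <- c("i", "j")
BOUND_LABELS <- c("a", "b", "c", "d", "e", "f", "g", "h")

new_factor <- function(sym, dt = 0L, derivs = character(), comps = character()) {
  list(sym = sym, dt = as.integer(dt), derivs = derivs, comps = comps)
}

new_monomial <- function(coef, factors) list(coef = coef, factors = factors)

factor_order <- function(f) f$dt + length(f$derivs)

mono_labels <- function(mono) {
  unlist(lapply(mono$factors, function(f) c(f$derivs, f$comps)))
}

mono_parity <- function(mono) {
  sum(vapply(mono$factors, function(f) f$sym == "n", logical(1))) %% 2L
}

mono_n_fields <- function(mono) {
  sum(vapply(mono$factors, function(f) f$sym %in% c("u", "n"), logical(1)))
}

factor_string <- function(f) {
  paste0(f$sym, "[t", f$dt, "|", paste(f$derivs, collapse = ""), "|",
         paste(f$comps, collapse = ""), "]")
}

# --- canonicalization -------------------------------------------------------

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (p in perms_of(v[-k])) out <- c(out, list(c(v[k], p)))
  }
  out
}

# Canonical form: contracted labels renamed over all permutations, spatial
# derivative labels sorted within each factor (derivatives commute), delta
# components sorted, epsilon components sorted with a sign, factors sorted by
# their rendered string; the lexicographically smallest rendering wins.
canonical_monomial <- function(mono) {
  fac <- Filter(function(f) f$sym != "one", mono$factors)
  if (length(fac) == 0L) {
    return(list(coef = mono$coef, factors = list(), key = "1"))
  }
  labs <- unlist(lapply(fac, function(f) c(f$derivs, f$comps)))
  bound <- sort(unique(labs[!(labs %in% FREE_LABELS)]))
  stopifnot(length(bound) <= length(BOUND_LABELS))
  best <- NULL
  for (perm in perms_of(bound)) {
    map <- stats::setNames(BOUND_LABELS[seq_along(bound)], perm)
    sign <- 1
    fs <- lapply(fac, function(f) {
      f$derivs <- sort(unname(ifelse(f$derivs %in% names(map), map[f$derivs], f$derivs)))
      f$comps <- unname(ifelse(f$comps %in% names(map), map[f$comps], f$comps))
      f
    })
    for (k in seq_along(fs)) {
      f <- fs[[k]]
      if (f$sym == "delta") fs[[k]]$comps <- sort(f$comps)
      if (f$sym == "eps" && is.unsorted(f$comps)) {
        fs[[k]]$comps <- sort(f$comps)
        sign <- -sign
      }
    }
    strs <- vapply(fs, factor_string, character(1))
    o <- order(strs)
    key <- paste(strs[o], collapse = ";")
    if (is.null(best) || key < best$key) {
      best <- list(coef = mono$coef * sign, factors = fs[o], key = key)
    }
  }
  best
}

# --- unit-director simplification -------------------------------------------

# Rewrites using n.n = 1 and n . (d n) = 0 (any first derivative), and
# n_a D1 D2 n_a = -(D1 n_b)(D2 n_b) for second derivatives.
# Returns NULL when the monomial vanishes identically.
simplify_unit_director <- function(mono) {
  repeat {
    fac <- mono$factors
    plain_n <- which(vapply(fac, function(f) f$sym == "n" && factor_order(f) == 0L, logical(1)))
    changed <- FALSE
    # n_a n_a -> 1
    if (length(plain_n) >= 2L) {
      for (p1 in plain_n) {
        for (p2 in plain_n[plain_n > p1]) {
          if (identical(fac[[p1]]$comps, fac[[p2]]$comps) &&
              !(fac[[p1]]$comps %in% FREE_LABELS)) {
            mono$factors <- fac[-c(p1, p2)]
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    if (changed) next
    # n_a (D n)_a
    if (length(plain_n) >= 1L) {
      deriv_n <- which(vapply(fac, function(f) f$sym == "n" && factor_order(f) > 0L, logical(1)))
      for (p1 in plain_n) {
        for (p2 in deriv_n) {
          if (identical(fac[[p1]]$comps, fac[[p2]]$comps) &&
              !(fac[[p1]]$comps %in% FREE_LABELS)) {
            ord <- factor_order(fac[[p2]])
            if (ord == 1L) return(NULL)
            # second derivative: split D1 D2 and rewrite
            f2 <- fac[[p2]]
            used <- mono_labels(mono)
            fresh <- setdiff(BOUND_LABELS, used)[1]
            ds <- c(f2$derivs, if (f2$dt > 0L) "t" else NULL)
            stopifnot(length(ds) == 2L)
            mk <- function(dd) {
              if (dd == "t") new_factor("n", dt = 1L, comps = fresh)
              else new_factor("n", derivs = dd, comps = fresh)
            }
            mono$factors <- c(fac[-c(p1, p2)], list(mk(ds[1]), mk(ds[2])))
            mono$coef <- -mono$coef
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    if (!changed) break
  }
  mono
}

# --- terms ------------------------------------------------------------------

# Combine monomials into a canonical term: canonicalize + simplify each,
# merge duplicates, drop negligible coefficients, normalize so the first
# monomial (in key order) has coefficient 1.  Returns NULL for the zero term.
make_term <- function(monomials, rank, parity, class) {
  canon <- list()
  for (m in monomials) {
    m <- simplify_unit_director(m)
    if (is.null(m)) next
    cm <- canonical_monomial(m)
    k <- cm$key
    if (!is.null(canon[[k]])) canon[[k]]$coef <- canon[[k]]$coef + cm$coef
    else canon[[k]] <- cm
  }
  canon <- Filter(function(m) abs(m$coef) > 1e-12, canon)
  if (length(canon) == 0L) return(NULL)
  canon <- canon[order(names(canon))]
  scale <- canon[[1]]$coef
  canon <- lapply(canon, function(m) { m$coef <- m$coef / scale; m })
  key <- paste(vapply(canon, function(m) paste0(signif(m$coef, 10), "*", m$key),
                      character(1)), collapse = " + ")
  structure(list(monomials = unname(canon), rank = rank, parity = parity,
                 class = class, key = key, label = NULL),
            class = "library_term")
}

term_complexity <- function(term) {
  m <- term$monomials[[1]]
  c(fields = mono_n_fields(m),
    derivs = sum(vapply(m$factors, factor_order, numeric(1))))
}

#' @export
format.library_term <- function(x, ...) pretty_term(x)

#' @export
print.library_term <- function(x, ...) {
  cat(pretty_term(x), "\n")
  invisible(x)
}

#' Render a library term in index notation
#'
#' @param term a library term.
#' @return a single string such as `"u_a d_a n_i"`.
#' @export
pretty_term <- function(term) {
  render_mono <- function(m, with_coef = TRUE) {
    if (length(m$factors) == 0L) body <- "1"
    else {
      body <- paste(vapply(m$factors, function(f) {
        pre <- paste0(c(rep("d_t ", f$dt),
                        if (length(f$derivs)) paste0("d_", f$derivs, " ")), collapse = "")
        nm <- switch(f$sym,
                     u = paste0("u_", f$comps),
                     n = paste0("n_", f$comps),
                     delta = paste0("delta_", paste(f$comps, collapse = "")),
                     eps = paste0("eps_", paste(f$comps, collapse = "")))
        paste0(pre, nm)
      }, character(1)), collapse = " ")
    }
    if (!with_coef) return(body)
    co <- m$coef
    if (abs(co - 1) < 1e-10) body
    else if (abs(co + 1) < 1e-10) paste0("-", body)
    else paste0(format(co, digits = 3), " ", body)
  }
  parts <- vapply(term$monomials, render_mono, character(1))
  out <- parts[1]
  for (p in parts[-1]) {
    out <- if (startsWith(p, "-")) paste0(out, " - ", substring(p, 2)) else paste0(out, " + ", p)
  }
  out
}

#' Library generation bounds
#'
#' The grammar enumerates products of u, n and their derivatives with all
#' inequivalent index contractions.  The default bounds are the smallest
#' that cover the incompressibility, director-evolution and stress-balance
#' relations of the active nematic (which require up to five field factors,
#' e.g. `(n A n) n_i n_j`) while keeping second-derivative terms (candidate
#' elastic contributions) available.
#'
#' @param rank tensor rank: 0, 1 or 2.
#' @param parity `"even"` or `"odd"` power of the director.
#' @param class symmetry class: `"scalar"`, `"vector"`,
#'   `"symmetric-traceless"` or `"antisymmetric"`; defaults to the natural
#'   class for ranks 0 and 1.
#' @param max_factors maximum number of u/n field factors (default 5).
#' @param max_deriv maximum total derivative order (default 2).
#' @param max_dt maximum time-derivative order (default 1).
#' @param max_derived maximum number of derivative-bearing factors (default 2).
#' @param max_deriv_multi maximum total derivative order for terms with more
#'   than two field factors (default 1): gradient-squared and Laplacian
#'   (elastic-type) candidates live at low factor order, while the
#'   high-factor-order nematic couplings carry a single velocity gradient.
#'   Keeps libraries at the tens-of-terms scale at which combinatorial
#'   validation stays exact.
#' @param max_plain_n,max_plain_u maximum underived n and u factors.
#' @param include_constant include the constant term 1 (rank 0 only).
#' @param include_eps allow one Levi-Civita factor (chiral terms; off by
#'   default, matching a reflection-symmetric system).
#' @return object of class `library_spec`.
#' @export
library_spec <- function(rank, parity, class = NULL,
                         max_factors = 5L, max_deriv = 2L, max_dt = 1L,
                         max_derived = 2L, max_deriv_multi = 1L,
                         max_plain_n = 4L, max_plain_u = 2L,
                         include_constant = (rank == 0L), include_eps = FALSE) {
  if (!rank %in% 0:2) stop("rank must be 0, 1 or 2")
  if (!parity %in% c("even", "odd")) stop("parity must be 'even' or 'odd'")
  if (is.null(class)) {
    class <- switch(rank + 1L, "scalar", "vector", "symmetric-traceless")
  }
  ok <- switch(class, scalar = rank == 0L, vector = rank == 1L,
               `symmetric-traceless` = rank == 2L, antisymmetric = rank == 2L,
               FALSE)
  if (!ok) stop("symmetry class inconsistent with rank")
  if (max_factors < 1L || max_deriv < 0L) stop("bounds must be positive")
  structure(list(rank = as.integer(rank), parity = parity, class = class,
                 max_factors = as.integer(max_factors),
                 max_deriv = as.integer(max_deriv), max_dt = as.integer(max_dt),
                 max_derived = as.integer(max_derived),
                 max_deriv_multi = as.integer(max_deriv_multi),
                 max_plain_n = as.integer(max_plain_n),
                 max_plain_u = as.integer(max_plain_u),
                 include_constant = include_constant,
                 include_eps = include_eps),
            class = "library_spec")
}

# All perfect matchings of a set of slot ids.
matchings_of <- function(ids) {
  if (length(ids) == 0L) return(list(list()))
  if (length(ids) %% 2L == 1L) return(list())
  first <- ids[1]
  rest <- ids[-1]
  out <- list()
  for (k in seq_along(rest)) {
    pair <- list(c(first, rest[k]))
    for (sub in matchings_of(rest[-k])) out <- c(out, list(c(pair, sub)))
  }
  out
}

#' Generate a symmetry-constrained term library
#'
#' Enumerates all products of field factors within the spec's bounds,
#' contracts indices in every inequivalent way down to the target rank,
#' applies the irreducible projection for rank-2 classes, filters by nematic
#' parity, simplifies with the unit-director identities, canonicalizes and
#' deduplicates.  Numeric (fingerprint) deduplication of linearly dependent
#' survivors is a separate step, [fingerprint_dedup()].
#'
#' @param spec a [library_spec()].
#' @return object of class `term_library`.
#' @export
generate_library <- function(spec) {
  # derivative-bearing factor types (sym, dt, nsp)
  dtypes <- list()
  for (sym in c("u", "n")) {
    for (dt in 0:spec$max_dt) {
      for (nsp in 0:min(2L, spec$max_deriv)) {
        if (dt + nsp >= 1L && dt + nsp <= spec$max_deriv) {
          dtypes <- c(dtypes, list(list(sym = sym, dt = dt, nsp = nsp)))
        }
      }
    }
  }
  dmultis <- list(list())
  if (spec$max_derived >= 1L) {
    for (k in seq_along(dtypes)) dmultis <- c(dmultis, list(dtypes[k]))
  }
  if (spec$max_derived >= 2L) {
    for (k1 in seq_along(dtypes)) for (k2 in k1:length(dtypes)) {
      pair <- c(dtypes[k1], dtypes[k2])
      ords <- vapply(pair, function(d) d$dt + d$nsp, numeric(1))
      dts <- vapply(pair, function(d) d$dt, numeric(1))
      if (sum(ords) <= spec$max_deriv && sum(dts) <= spec$max_dt) {
        dmultis <- c(dmultis, list(pair))
      }
    }
  }
  rank <- spec$rank
  free <- FREE_LABELS[seq_len(rank)]
  raw <- list()
  n_raw <- 0L
  add_candidate <- function(mono) {
    n_raw <<- n_raw + 1L
    if (n_raw > 10000L) {
      stop("library bounds generate more than 10^4 raw terms; tighten the spec")
    }
    term <- project_term(mono, spec)
    if (!is.null(term)) raw[[term$key]] <<- term
  }
  eps_opts <- if (spec$include_eps) 0:1 else 0L
  for (kn in 0:spec$max_plain_n) {
    for (ku in 0:spec$max_plain_u) {
      for (neps in eps_opts) {
        for (dm in dmultis) {
          nfac <- kn + ku + length(dm)
          if (nfac < 1L || nfac > spec$max_factors) next
          totd <- sum(vapply(dm, function(d) d$dt + d$nsp, numeric(1)))
          if (nfac > 2L && totd > spec$max_deriv_multi) next
          par <- (kn + sum(vapply(dm, function(d) d$sym == "n", numeric(1)))) %% 2L
          if (par != (if (spec$parity == "odd") 1L else 0L)) next
          nslots <- kn + ku + 2L * neps + sum(vapply(dm, function(d) 1L + d$nsp, integer(1)))
          if (nslots < rank || (nslots - rank) %% 2L != 0L) next
          # build slot table: one row per index slot
          slots <- list()
          fid <- 0L
          add_fac <- function(sym, dt, nsp) {
            fid <<- fid + 1L
            if (nsp > 0) for (q in seq_len(nsp)) slots[[length(slots) + 1L]] <<- c(fid, 1L)  # deriv slot
            slots[[length(slots) + 1L]] <<- c(fid, 0L)  # component slot
            list(id = fid, sym = sym, dt = dt, nsp = nsp)
          }
          facs <- list()
          for (q in seq_len(kn)) facs <- c(facs, list(add_fac("n", 0L, 0L)))
          for (q in seq_len(ku)) facs <- c(facs, list(add_fac("u", 0L, 0L)))
          if (neps == 1L) {
            fid <- fid + 1L
            slots[[length(slots) + 1L]] <- c(fid, 0L)
            slots[[length(slots) + 1L]] <- c(fid, 0L)
            facs <- c(facs, list(list(id = fid, sym = "eps", dt = 0L, nsp = 0L)))
          }
          for (dd in dm) facs <- c(facs, list(add_fac(dd$sym, dd$dt, dd$nsp)))
          ns <- length(slots)
          # assign free labels to ordered distinct slots, pair the rest
          free_choices <- if (rank == 0L) list(integer(0))
            else if (rank == 1L) as.list(seq_len(ns))
            else {
              fc <- list()
              for (s1 in seq_len(ns)) for (s2 in seq_len(ns)) {
                if (s1 != s2) fc <- c(fc, list(c(s1, s2)))
              }
              fc
            }
          for (fc in free_choices) {
            remaining <- setdiff(seq_len(ns), fc)
            for (mt in matchings_of(remaining)) {
              lab <- character(ns)
              if (rank >= 1L) lab[fc[1]] <- "i"
              if (rank == 2L) lab[fc[2]] <- "j"
              bl <- BOUND_LABELS
              for (q in seq_along(mt)) {
                lab[mt[[q]][1]] <- bl[q]
                lab[mt[[q]][2]] <- bl[q]
              }
              # build factors with labels
              fobj <- list()
              for (ff in facs) {
                srows <- which(vapply(slots, function(s) s[1] == ff$id, logical(1)))
                if (ff$sym == "eps") {
                  fobj <- c(fobj, list(new_factor("eps", comps = lab[srows])))
                } else {
                  dsl <- srows[seq_len(ff$nsp)]
                  csl <- srows[length(srows)]
                  fobj <- c(fobj, list(new_factor(ff$sym, dt = ff$dt,
                                                  derivs = lab[dsl],
                                                  comps = lab[csl])))
                }
              }
              add_candidate(new_monomial(1, fobj))
            }
          }
        }
      }
    }
  }
  terms <- unname(raw)
  has_const <- any(vapply(terms, function(t) t$key == "1*1", logical(1)))
  if (rank == 0L && spec$include_constant && !has_const) {
    terms <- c(terms, list(make_term(list(new_monomial(1, list())), 0L,
                                     spec$parity, "scalar")))
  }
  # deterministic order: simplest first, then by key
  cx <- t(vapply(terms, term_complexity, numeric(2)))
  keys <- vapply(terms, function(t) t$key, character(1))
  o <- order(cx[, 1], cx[, 2], keys)
  terms <- terms[o]
  structure(list(spec = spec, terms = terms, removed = list()),
            class = "term_library")
}

# Apply the irreducible rank-2 projection (or pass rank 0/1 through),
# returning a canonical term or NULL.
project_term <- function(mono, spec) {
  rank <- spec$rank
  if (rank < 2L) {
    return(make_term(list(mono), rank, spec$parity, spec$class))
  }
  swap_free <- function(m) {
    m$factors <- lapply(m$factors, function(f) {
      f$derivs <- chartr("ij", "ji", f$derivs)
      f$comps <- chartr("ij", "ji", f$comps)
      f
    })
    m
  }
  contract_free <- function(m) {
    used <- mono_labels(m)
    fresh <- setdiff(BOUND_LABELS, used)[1]
    m$factors <- lapply(m$factors, function(f) {
      f$derivs[f$derivs %in% c("i", "j")] <- fresh
      f$comps[f$comps %in% c("i", "j")] <- fresh
      f
    })
    m
  }
  mT <- swap_free(mono)
  if (spec$class == "antisymmetric") {
    monos <- list(new_monomial(0.5, mono$factors), new_monomial(-0.5, mT$factors))
  } else {
    mTr <- contract_free(mono)
    delta <- new_factor("delta", comps = c("i", "j"))
    monos <- list(new_monomial(0.5, mono$factors), new_monomial(0.5, mT$factors),
                  new_monomial(-0.5, c(list(delta), mTr$factors)))
  }
  make_term(monos, rank, spec$parity, spec$class)
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf("term_library: %d terms (rank %d, %s parity, %s)\n",
              length(x$terms), x$spec$rank, x$spec$parity, x$spec$class))
  for (k in seq_along(x$terms)) cat(sprintf("  [%2d] %s\n", k, pretty_term(x$terms[[k]])))
  invisible(x)
}

#' Number of independent tensor components evaluated per term
#' @keywords internal
class_components <- function(class) {
  switch(class,
         scalar = list(integer(0)),
         vector = list(1L, 2L),
         `symmetric-traceless` = list(c(1L, 1L), c(1L, 2L)),
         antisymmetric = list(c(1L, 2L)))
}

#' Serialize a term library to JSON
#' @param library a `term_library`.
#' @param path output path.
#' @export
write_library_json <- function(library, path) {
  obj <- list(
    spec = unclass(library$spec),
    terms = lapply(library$terms, function(t) {
      list(key = t$key, label = pretty_term(t), rank = t$rank,
           parity = t$parity, class = t$class,
           monomials = lapply(t$monomials, function(m) {
             list(coef = m$coef, factors = lapply(m$factors, function(f) {
               list(sym = f$sym, dt = f$dt, derivs = as.list(f$derivs),
                    comps = as.list(f$comps))
             }))
           }))
    }),
    removed = library$removed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a term library from JSON written by [write_library_json()]
#' @param path JSON path.
#' @export
read_library_json <- function(path) {
  obj <- jsonlite::read_json(path)
  spec <- do.call(library_spec, obj$spec[c("rank", "parity", "class", "max_factors",
                                           "max_deriv", "max_dt", "max_derived",
                                           "max_deriv_multi",
                                           "max_plain_n", "max_plain_u",
                                           "include_constant", "include_eps")])
  terms <- lapply(obj$terms, function(t) {
    structure(list(
      monomials = lapply(t$monomials, function(m) {
        list(coef = m$coef, factors = lapply(m$factors, function(f) {
          new_factor(f$sym, dt = f$dt, derivs = unlist(f$derivs) %||% character(),
                     comps = unlist(f$comps) %||% character())
        }), key = NULL)
      }),
      rank = t$rank, parity = t$parity, class = t$class, key = t$key,
      label = t$label), class = "library_term")
  })
  structure(list(spec = spec, terms = terms, removed = obj$removed),
            class = "term_library")
}
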