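# Minimal discrete factor algebra used by exact inference and EM.
# A factor is a list(vars, card, val): `vars` the variable names, `card` the
# named state counts, `val` a numeric vector in mixed-radix layout with
# vars[1] varying fastest.

new_factor <- function(vars, card, val) {
  stopifnot(length(val) == prod(card), length(vars) == length(card))
  list(vars = vars, card = setNames(as.integer(card), vars), val = as.numeric(val))
}

f_strides <- function(card) {
  k <- length(card)
  if (k == 0) return(integer(0))
  setNames(cumprod(c(1L, unname(card[-k]))), names(card))
}

# digit vector (0-based state index) of `var` across all cells of a factor
# with cardinalities `card`
f_digits <- function(card, var) {
  n <- prod(card)
  s <- f_strides(card)[[var]]
  k <- card[[var]]
  rep(rep.int(0:(k - 1L), rep.int(s, k)), length.out = n)
}

f_product <- function(f, g) {
  if (length(f$vars) == 0) return(new_factor(g$vars, g$card, g$val * f$val))
  if (length(g$vars) == 0) return(new_factor(f$vars, f$card, f$val * g$val))
  vars_u <- union(f$vars, g$vars)
  card_u <- setNames(integer(length(vars_u)), vars_u)
  card_u[f$vars] <- f$card
  card_u[g$vars] <- g$card
  sf <- f_strides(f$card); sg <- f_strides(g$card)
  n <- prod(card_u)
  idx_f <- rep.int(1, n); idx_g <- rep.int(1, n)
  for (v in vars_u) {
    d <- f_digits(card_u, v)
    if (v %in% f$vars) idx_f <- idx_f + d * sf[[v]]
    if (v %in% g$vars) idx_g <- idx_g + d * sg[[v]]
  }
  new_factor(vars_u, card_u, f$val[idx_f] * g$val[idx_g])
}

f_sumout <- function(f, var) {
  i <- match(var, f$vars)
  stopifnot(!is.na(i))
  if (length(f$vars) == 1L) {
    return(new_factor(character(0), integer(0), sum(f$val)))
  }
  a <- array(f$val, dim = unname(f$card))
  perm <- c(i, setdiff(seq_along(f$vars), i))
  a <- aperm(a, perm)
  dim(a) <- c(f$card[[i]], length(f$val) / f$card[[i]])
  new_factor(f$vars[-i], f$card[-i], colSums(a))
}

# condition on var = state (1-based index); drops the variable
f_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  a <- array(f$val, dim = unname(f$card))
  args <- rep(list(quote(expr = )), length(f$vars))
  args[[i]] <- state
  a <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  new_factor(f$vars[-i], f$card[-i], as.vector(a))
}

# reorder a factor's dimensions to `vars`
f_permute <- function(f, vars) {
  stopifnot(setequal(vars, f$vars))
  if (identical(vars, f$vars)) return(f)
  a <- array(f$val, dim = unname(f$card))
  perm <- match(vars, f$vars)
  new_factor(vars, f$card[vars], as.vector(aperm(a, perm)))
}
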