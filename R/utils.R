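# shared internal helpers

# round-half-up, used for printed-table comparisons (base round() is
# round-half-even and disagrees at e.g. 0.2105 -> 0.211)
roundHalfUp <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# stable small hash of an identifier string, < 2^31
idHash <- function(id) {
  v <- utf8ToInt(as.character(id))
  as.integer(sum(v * seq_along(v)) %% 1000003)
}

# expand the single global seed into a per-stream substream seed so that
# adding a tumor does not perturb the draws of any other tumor
substreamSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 65521 * 31627 + idHash(stream)) %% 2147483629)
}

# moving-window median over one chromosome: positions sorted ascending,
# window centered at each position, inclusive on both ends
movingMedian <- function(pos, values, windowBp) {
  stopifnot(!is.unsorted(pos))
  half <- windowBp / 2
  left <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  right <- findInterval(pos + half, pos)
  vapply(seq_along(pos),
         function(i) stats::median(values[left[i]:right[i]]),
         numeric(1))
}

requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}
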