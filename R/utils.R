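# Bind a list of same-shaped named lists of column vectors into one tibble.
# Cheaper than building a tibble per group in simulation hot loops.
bind_row_lists <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  nms <- names(rows[[1]])
  cols <- lapply(nms, function(nm) {
    do.call(c, lapply(rows, `[[`, nm))
  })
  names(cols) <- nms
  tibble::as_tibble(cols)
}
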