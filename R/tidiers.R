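# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a coexpression network
#'
#' One row per gene: module label, own-module membership and intramodular
#' connectivity.
#'
#' @param x a `coex_network`.
#' @param ... unused.
#' @return tibble: `gene`, `module`, `kme`, `kim`.
#' @method tidy coex_network
#' @export
tidy.coex_network <- function(x, ...) {
  out <- left_join(x$modules, select(x$kim, "gene", "kim"), by = "gene")
  if (!is.null(x$kme)) {
    own <- vapply(seq_len(nrow(out)), function(i) {
      mod <- out$module[i]
      if (mod == "grey" || !mod %in% names(x$kme)) return(NA_real_)
      x$kme[[mod]][x$kme$gene == out$gene[i]]
    }, numeric(1))
    out$kme <- own
  } else {
    out$kme <- NA_real_
  }
  select(out, "gene", "module", "kme", "kim")
}

#' @rdname tidy.coex_network
#' @return for `glance()`: one row with `n_genes`, `n_modules`,
#'   `n_background`, `power`, `median_module_size`.
#' @method glance coex_network
#' @export
glance.coex_network <- function(x, ...) {
  sizes <- table(x$modules$module)
  mod_sizes <- sizes[names(sizes) != "grey"]
  tibble(
    n_genes = nrow(x$modules),
    n_modules = length(mod_sizes),
    n_background = if ("grey" %in% names(sizes)) unname(sizes[["grey"]]) else 0L,
    power = x$power,
    median_module_size = if (length(mod_sizes)) median(as.numeric(mod_sizes)) else NA_real_
  )
}

#' Tidy a module-preservation result
#'
#' `tidy()` returns the long per-statistic table (observed value, permutation
#' mean/SD and Z per module and statistic); `glance()` returns the composite
#' summary (one row per module).
#'
#' @param x a `module_preservation`.
#' @param ... unused.
#' @method tidy module_preservation
#' @export
tidy.module_preservation <- function(x, ...) x$stats

#' @rdname tidy.module_preservation
#' @method glance module_preservation
#' @export
glance.module_preservation <- function(x, ...) x$summary
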