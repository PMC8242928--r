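# Reproductions of the analysis's headline tables and threshold results as
# tidy tibbles, plus file export with a JSON run manifest so every output is
# traceable to the parameters that produced it.

.fmt_leading <- function(coef, power) {
  co <- if (coef == "1") "" else paste0(coef, " ")
  if (power == 0) coef
  else if (power == 1) paste0(co, "eps")
  else paste0(co, "eps^", power)
}

#' Best-response table (exact small-error replica)
#'
#' One row per resident strategy: its best response among the sixteen
#' memory-one pure strategies, the exact payoff series of that response
#' (limit and `eps^1` coefficient), and the self-response ("dagger") flag.
#' At generic costs the daggered set is AllD plus Grim-Trigger-1 when
#' `c > 1/3` plus WSLS when `c < 1/2`.
#'
#' @param game a [game_params()] object.
#' @param order series order.
#' @return A tibble; see [response_table()] for the columns, with `dagger`
#'   as an alias of `is_self`.
#' @examples
#' report_table1(game_params(0.4))
#' @export
report_table1 <- function(game, order = 2) {
  tb <- response_table(game, order = order)
  bits <- strategies()$bits
  dplyr::mutate(tb,
                resident_bits = bits[.data$resident + 1L],
                dagger = .data$is_self,
                .after = "resident_name")
}

#' Self-play signature table (leading-order replica)
#'
#' One row per strategy: the leading-order term of each stationary-state
#' frequency in its self-play (e.g. `"1/4"`, `"2 eps"`, `"eps^2"`), and the
#' observability category I/II/III.
#'
#' @return A tibble with columns `category`, `strategy`, `name`, `bits`,
#'   `v_cc`, `v_cd`, `v_dc`, `v_dd` (leading-order strings), `n_observable`.
#' @examples
#' report_table2()
#' @export
report_table2 <- function() {
  bits <- strategies()$bits
  rows <- purrr::map_dfr(0:15, function(i) {
    ls <- limit_stationary(i, i)
    lead <- vapply(1:4, function(k) .fmt_leading(ls$leading_coef[k], ls$leading_power[k]), "")
    tibble::tibble(
      strategy = i, name = strategy_name(i), bits = bits[i + 1L],
      v_cc = lead[1], v_cd = lead[2], v_dc = lead[3], v_dd = lead[4],
      n_observable = sum(ls$observable),
      category = classify_signature(i)$category
    )
  })
  dplyr::arrange(dplyr::relocate(rows, "category"), .data$category, .data$strategy)
}

#' Critical cost thresholds of the analysis
#'
#' Recomputes, as exact rationals, every critical cooperation cost at which
#' the model's verdicts switch: the self-best-response thresholds of
#' Grim-Trigger-1 (1/3) and WSLS (1/2), the best-response switch of d11
#' (1/2), the best-looking-response switches under the uniform priors over
#' the defect-looking (16/33) and cooperate-looking (2/9) candidate sets, and
#' the cost bound above which the WSLS prior region disappears (1/2).
#'
#' @return A tibble with columns `context`, `threshold` (exact string),
#'   `threshold_num`, `below`, `above` (the competing strategies).
#' @examples
#' report_thresholds()
#' @export
report_thresholds <- function() {
  rows <- list(
    c(list(context = "self-response switch of GT1 (d8)"), critical_cost(8, 0.1, 0.9)),
    c(list(context = "self-response switch of WSLS (d9)"), critical_cost(9, 0.1, 0.9)),
    c(list(context = "best-response switch of d11"), critical_cost(11, 0.1, 0.9)),
    c(list(context = "best-looking switch, uniform prior {d0,d6,d8}"),
      belief_switch_cost(belief_uniform(c(0, 6, 8)))),
    c(list(context = "best-looking switch, uniform prior {d9,d14,d15}"),
      belief_switch_cost(belief_uniform(c(9, 14, 15))))
  )
  out <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(context = r$context, threshold = format(r$critical),
                   threshold_num = as.double(r$critical),
                   below = paste0("d", r$low_side), above = paste0("d", r$high_side))
  })
  feas <- wsls_feasibility_cost()
  dplyr::bind_rows(out, tibble::tibble(
    context = "WSLS prior-region feasibility bound {d9,d14,d15}",
    threshold = format(feas), threshold_num = as.double(feas),
    below = "d9 region non-empty", above = "d9 region empty"))
}

#' Write a report with a run manifest
#'
#' Writes a tibble as CSV (or JSON) and a `<path>.manifest.json` sidecar
#' recording the generating parameters, package version, timestamp and file
#' checksum, so the output is traceable and byte-reproducible given the same
#' parameters and seed.
#'
#' @param x a data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param params named list of generating parameters recorded in the
#'   manifest (cost, epsilon, seeds, grid steps, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json"), params = list()) {
  format <- match.arg(format)
  x_out <- dplyr::mutate(as.data.frame(x), dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, "", collapse = ";")))
  if (format == "csv") {
    utils::write.csv(x_out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x_out, path, dataframe = "rows", digits = NA)
  }
  manifest <- list(
    file = basename(path),
    format = format,
    params = params,
    package = "scenepd",
    version = as.character(utils::packageVersion("scenepd")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
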