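# Two-parent + F2 trait simulation with additive inheritance and a target
# broad-sense heritability.

#' Trait generation model
#'
#' Describes a quantitative trait in two parental lines and their F2. F2
#' values are midparent + genetic deviate + environmental deviate, where the
#' environmental variance is the Mahmud-Kramer estimate
#' `V_E = sqrt(V_P1 * V_P2)` (geometric mean of the parental variances) and
#' the genetic variance is chosen so the expected broad-sense heritability
#' `V_G / (V_G + V_E)` equals `target_H2`. Inheritance is additive only; no
#' dominance term is modelled (no magnitude for it is reported anywhere).
#'
#' @param parent1_mean,parent1_sd,parent2_mean,parent2_sd parental trait
#'   distributions (trait units).
#' @param target_H2 target broad-sense heritability in `[0, 1)`.
#' @param n_per_parent,n_f2 sample sizes (defaults emulate the mapping
#'   population: 129 F2 plants, 33 parental plants split across lines).
#' @param trait trait name used for the value column.
#' @param seed integer seed.
#' @return object of class `trait_gen_model`.
#' @export
trait_gen_model <- function(parent1_mean, parent1_sd,
                            parent2_mean, parent2_sd,
                            target_H2 = 0.6,
                            n_per_parent = 16L, n_f2 = 129L,
                            trait = "trait", seed = 1L) {
  if (!is_scalar_number(parent1_sd) || !is_scalar_number(parent2_sd) ||
      parent1_sd <= 0 || parent2_sd <= 0) {
    cf_stop("parental sds must be positive", "cf_parameter_error")
  }
  if (!is_scalar_number(target_H2) || target_H2 < 0 || target_H2 >= 1) {
    cf_stop("target_H2 must lie in [0, 1)", "cf_parameter_error")
  }
  if (n_per_parent < 1L || n_f2 < 1L) {
    cf_stop("sample sizes must be >= 1", "cf_parameter_error")
  }
  structure(
    list(
      parent1_mean = parent1_mean, parent1_sd = parent1_sd,
      parent2_mean = parent2_mean, parent2_sd = parent2_sd,
      target_H2 = target_H2,
      n_per_parent = as.integer(n_per_parent), n_f2 = as.integer(n_f2),
      trait = trait, seed = as.integer(seed)
    ),
    class = "trait_gen_model"
  )
}

#' Generate a two-parent + F2 trait table
#'
#' @param model a [trait_gen_model()].
#' @return a `data.frame` of class `trait_table` with columns `plant_id`,
#'   `generation` (factor P1/P2/F2) and one numeric trait column named after
#'   `model$trait`.
#' @examples
#' tab <- generate_trait_table(trait_gen_model(110.7, 6.9, 95, 15.2, seed = 7))
#' table(tab$generation)
#' @export
generate_trait_table <- function(model) {
  stopifnot(inherits(model, "trait_gen_model"))
  m <- model
  with_seed(m$seed, {
    v_e <- m$parent1_sd * m$parent2_sd # sqrt(V_P1 * V_P2)
    v_g <- if (m$target_H2 > 0) v_e * m$target_H2 / (1 - m$target_H2) else 0
    midparent <- (m$parent1_mean + m$parent2_mean) / 2
    p1 <- stats::rnorm(m$n_per_parent, m$parent1_mean, m$parent1_sd)
    p2 <- stats::rnorm(m$n_per_parent, m$parent2_mean, m$parent2_sd)
    f2 <- midparent + stats::rnorm(m$n_f2, 0, sqrt(v_g)) +
      stats::rnorm(m$n_f2, 0, sqrt(v_e))
    tab <- data.frame(
      plant_id = sprintf(
        "%s_%03d",
        rep(c("P1", "P2", "F2"), c(m$n_per_parent, m$n_per_parent, m$n_f2)),
        c(seq_len(m$n_per_parent), seq_len(m$n_per_parent), seq_len(m$n_f2))
      ),
      generation = factor(
        rep(c("P1", "P2", "F2"), c(m$n_per_parent, m$n_per_parent, m$n_f2)),
        levels = c("P1", "P2", "F2")
      ),
      stringsAsFactors = FALSE
    )
    tab[[m$trait]] <- c(p1, p2, f2)
    class(tab) <- c("trait_table", "data.frame")
    attr(tab, "model") <- m
    tab
  })
}

#' Read/write trait tables as CSV
#'
#' CSV layout: header `plant_id, generation, <trait columns...>`.
#'
#' @param table a `trait_table` (or plain data.frame with those columns).
#' @param path file path.
#' @return `read_trait_table` returns a `trait_table`; `write_trait_table`
#'   returns `path` invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plant_id", "generation") %in% names(tab))) {
    cf_stop("trait table CSV must have plant_id and generation columns",
            "cf_validation_error")
  }
  bad <- setdiff(unique(tab$generation), c("P1", "P2", "F2"))
  if (length(bad)) {
    cf_stop(sprintf("unknown generation codes: %s", paste(bad, collapse = ", ")),
            "cf_validation_error")
  }
  tab$generation <- factor(tab$generation, levels = c("P1", "P2", "F2"))
  class(tab) <- c("trait_table", "data.frame")
  tab
}
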