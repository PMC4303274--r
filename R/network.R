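#' Enumerate the chemical species of a combinatorial allosteric model
#'
#' Enumerates every distinguishable state of the protein: per-lobe
#' conformation (T or R), calcium occupancy of each site (sites A and B on
#' the N lobe, C and D on the C-lobe; a lobe model has sites A and B
#' only), and at most one bound target per molecule. Intact calmodulin
#' with no targets yields the full 2 x 2 x 2^4 = 64 species; each
#' mutually exclusive target doubles the count by adding a bound copy of
#' every conformational/occupancy state.
#'
#' @param params [intact_params()] or [lobe_params()].
#' @param targets List of [intact_target_spec()] (intact) or
#'   [target_spec()] (lobe) objects; bound exclusively, one per molecule.
#' @return A tibble with columns `id`, conformation columns, one `occ_*`
#'   column per site, `n_ca`, and `target` (`NA` for target-free species).
#' @examples
#' nrow(enumerate_species(intact_params(
#'   lobe_params(3.226e5, 1.979e-8, 9.192e-5),
#'   lobe_params(8.616e3, 1.979e-8, 6.241e-5))))  # 64
#' @export
enumerate_species <- function(params, targets = list()) {
  if (inherits(targets, "target_spec") || inherits(targets, "intact_target_spec"))
    targets <- list(targets)
  tnames <- vapply(targets, function(t) t$name, "")
  if (anyDuplicated(tnames)) stop("duplicate target names")
  intact <- inherits(params, "intact_params")
  if (intact) {
    grid <- expand.grid(occ_D = 0:1, occ_C = 0:1, occ_B = 0:1, occ_A = 0:1,
                        conf_C = c("T", "R"), conf_N = c("T", "R"),
                        target = c(NA_character_, tnames),
                        stringsAsFactors = FALSE)
    grid <- grid[, c("conf_N", "conf_C", "occ_A", "occ_B", "occ_C", "occ_D",
                     "target")]
    grid$n_ca <- grid$occ_A + grid$occ_B + grid$occ_C + grid$occ_D
    grid$id <- paste0("CaM_", grid$conf_N, grid$conf_C, "_",
                      "A", grid$occ_A, "B", grid$occ_B,
                      "C", grid$occ_C, "D", grid$occ_D,
                      ifelse(is.na(grid$target), "",
                             paste0("_t", grid$target)))
  } else {
    stopifnot(inherits(params, "lobe_params"))
    grid <- expand.grid(occ_B = 0:1, occ_A = 0:1, conf = c("T", "R"),
                        target = c(NA_character_, tnames),
                        stringsAsFactors = FALSE)
    grid <- grid[, c("conf", "occ_A", "occ_B", "target")]
    grid$n_ca <- grid$occ_A + grid$occ_B
    grid$id <- paste0("Lobe_", grid$conf, "_",
                      "A", grid$occ_A, "B", grid$occ_B,
                      ifelse(is.na(grid$target), "",
                             paste0("_t", grid$target)))
  }
  tibble::as_tibble(grid[, c("id", setdiff(names(grid), "id"))])
}

## Dissociation constant of a target for the given species conformation.
target_K_for <- function(spec, species_row, intact) {
  if (intact) {
    conf <- paste0(species_row$conf_N, species_row$conf_C)
    spec[[paste0("K_", conf)]]
  } else {
    if (species_row$conf == "R") spec$K_Rt else spec$K_Tt
  }
}

#' Build the thermodynamically consistent reaction network
#'
#' Generates the reversible reaction network of the combinatorial model:
#' (i) per-site calcium binding with the microscopic dissociation constant
#' set by the owning lobe's current conformation (`K_R` or `K_T`), (ii)
#' concerted per-lobe conformational flips whose equilibrium constant is
#' the allosteric constant scaled by `c` for every calcium bound on that
#' lobe, and by the ratio of the target's conformation affinities when a
#' target is bound, and (iii) target binding to every conformation with
#' its conformation-specific constant. Equilibrium constants are derived
#' from a single thermodynamic potential, so the Wegscheider (detailed
#' balance) condition holds on every cycle by construction. Forward rate
#' constants are set to a uniform nominal value and backward rates derived
#' from the equilibrium constants; only equilibria are meaningful.
#'
#' @inheritParams enumerate_species
#' @param kf Nominal forward rate constant used for every reaction.
#' @return An object of class `cam_network`: list with `species` (tibble),
#'   `reactions` (tibble with `Keq` as association constant
#'   `[product]/([reactant][ligand])` for binding and `[R-form]/[T-form]`
#'   for flips), `params`, and `targets`.
#' @export
build_network <- function(params, targets = list(), kf = 1e6) {
  if (inherits(targets, "target_spec") || inherits(targets, "intact_target_spec"))
    targets <- list(targets)
  intact <- inherits(params, "intact_params")
  sp <- enumerate_species(params, targets)
  tmap <- stats::setNames(targets, vapply(targets, function(t) t$name, ""))
  site_cols <- grep("^occ_", names(sp), value = TRUE)
  sites <- sub("occ_", "", site_cols)
  lobe_of_site <- if (intact)
    c(A = "N", B = "N", C = "C", D = "C") else c(A = "lobe", B = "lobe")
  reactions <- list()
  add <- function(type, reactant, product, ligand, Keq) {
    reactions[[length(reactions) + 1]] <<- tibble::tibble(
      type = type, reactant = reactant, product = product,
      ligand = ligand, Keq = Keq)
  }
  key_cols <- setdiff(names(sp), c("id", "n_ca"))
  sp_key <- do.call(paste, c(sp[key_cols], sep = "|"))
  find_id <- function(row) sp$id[match(do.call(paste, c(row[key_cols], sep = "|")),
                                       sp_key)]
  lobe_pars <- function(lobe) {
    if (!intact) params else params[[lobe]]
  }
  for (k in seq_len(nrow(sp))) {
    row <- sp[k, ]
    ## calcium binding at each empty site
    for (s in sites) {
      if (row[[paste0("occ_", s)]] == 1) next
      lp <- lobe_pars(lobe_of_site[[s]])
      conf <- if (intact) row[[paste0("conf_", lobe_of_site[[s]])]] else row$conf
      Kd <- if (conf == "R") lp$K_R else lp$K_T
      prod_row <- row
      prod_row[[paste0("occ_", s)]] <- 1L
      add("ca_binding", row$id, find_id(prod_row), "Ca", 1 / Kd)
    }
    ## concerted flip of each lobe currently in T (reaction written T -> R)
    lobes <- if (intact) c("N", "C") else "lobe"
    for (lb in lobes) {
      conf_col <- if (intact) paste0("conf_", lb) else "conf"
      if (row[[conf_col]] != "T") next
      lp <- lobe_pars(lb)
      own_sites <- sites[lobe_of_site[sites] == lb]
      n_ca_lobe <- sum(unlist(row[paste0("occ_", own_sites)]))
      prod_row <- row
      prod_row[[conf_col]] <- "R"
      tfac <- 1
      if (!is.na(row$target)) {
        spec <- tmap[[row$target]]
        tfac <- target_K_for(spec, prod_row, intact) /
          target_K_for(spec, row, intact)
      }
      ## [T]/[R] = L * c^nCa * K_R-form / K_T-form  =>  Keq([R]/[T]) below
      add("flip", row$id, find_id(prod_row), NA_character_,
          1 / (lp$L * lp$c^n_ca_lobe * tfac))
    }
    ## target binding to every target-free species
    if (is.na(row$target)) {
      for (nm in names(tmap)) {
        prod_row <- row
        prod_row$target <- nm
        Kd <- target_K_for(tmap[[nm]], row, intact)
        add("target_binding", row$id, find_id(prod_row), nm, 1 / Kd)
      }
    }
  }
  reactions <- dplyr::bind_rows(reactions)
  reactions$id <- sprintf("re%04d", seq_len(nrow(reactions)))
  reactions$kf <- kf
  reactions$kr <- kf / reactions$Keq
  reactions <- reactions[, c("id", "type", "reactant", "product", "ligand",
                             "Keq", "kf", "kr")]
  structure(list(species = sp, reactions = reactions, params = params,
                 targets = targets, intact = intact),
            class = "cam_network")
}

#' @export
print.cam_network <- function(x, ...) {
  cat(sprintf("<cam_network> %s model: %d species, %d reactions, %d target(s)\n",
              if (x$intact) "intact CaM" else "lobe",
              nrow(x$species), nrow(x$reactions), length(x$targets)))
  invisible(x)
}

## Log statistical weight of every species relative to the apo reference,
## at 1 M standard ligand concentrations, assigned by breadth-first search
## over the reaction graph.
network_potentials <- function(network) {
  sp <- network$species
  re <- network$reactions
  phi <- stats::setNames(rep(NA_real_, nrow(sp)), sp$id)
  apo <- sp$id[sp$n_ca == 0 & is.na(sp$target) &
                 apply(sp[grep("^conf", names(sp))] == "T", 1, all)]
  phi[apo[1]] <- 0
  edges_from <- split(seq_len(nrow(re)), re$reactant)
  edges_to <- split(seq_len(nrow(re)), re$product)
  queue <- apo[1]
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (i in edges_from[[cur]]) {
      nxt <- re$product[i]
      if (is.na(phi[nxt])) {
        phi[nxt] <- phi[cur] + log(re$Keq[i])
        queue <- c(queue, nxt)
      }
    }
    for (i in edges_to[[cur]]) {
      nxt <- re$reactant[i]
      if (is.na(phi[nxt])) {
        phi[nxt] <- phi[cur] - log(re$Keq[i])
        queue <- c(queue, nxt)
      }
    }
  }
  if (anyNA(phi)) stop("network is not connected: unreachable species")
  phi
}

#' Wegscheider (detailed-balance) residuals of a network
#'
#' Checks thermodynamic consistency: assigns every species a potential by
#' spanning-tree traversal from the apo reference state and reports, for
#' every reaction, the discrepancy between its equilibrium constant and
#' the potential difference. A non-zero residual on any edge is exactly a
#' violation of the Wegscheider condition (the product of equilibrium
#' constants around some closed cycle differing from 1).
#'
#' @param network A [build_network()] result.
#' @return A tibble with columns `id`, `type`, `log_residual`.
#' @export
wegscheider_residuals <- function(network) {
  phi <- network_potentials(network)
  re <- network$reactions
  tibble::tibble(id = re$id, type = re$type,
                 log_residual = abs(log(re$Keq) -
                                      (phi[re$product] - phi[re$reactant])))
}

#' Equilibrium species concentrations of a network
#'
#' Computes equilibrium concentrations from statistical weights relative
#' to the apo reference state, with calcium clamped at its free value and
#' target free concentrations solved from mass balance (conservation of
#' protein and target totals).
#'
#' @param network A [build_network()] result.
#' @param protein_total Total protein concentration (molar).
#' @param target_totals Named or positional totals (molar), one per
#'   network target.
#' @param ca_free Clamped free calcium concentration (molar, scalar).
#' @return A tibble of species with `concentration` (molar), plus
#'   attributes `saturation` (fractional calcium saturation),
#'   `free_targets`, and `ca_free`.
#' @export
network_equilibrium <- function(network, protein_total, target_totals = numeric(),
                                ca_free) {
  stopifnot(inherits(network, "cam_network"), length(ca_free) == 1)
  tnames <- vapply(network$targets, function(t) t$name, "")
  if (length(target_totals) != length(tnames))
    stop("need one total per network target")
  phi <- network_potentials(network)
  sp <- network$species
  w0 <- exp(phi[sp$id]) * ca_free^sp$n_ca
  weight_at <- function(free) {
    fac <- rep(1, nrow(sp))
    for (i in seq_along(tnames))
      fac[!is.na(sp$target) & sp$target == tnames[i]] <- free[i]
    w0 * fac
  }
  free <- as.numeric(target_totals)
  if (length(tnames) > 0 && protein_total > 0 && any(target_totals > 0)) {
    for (sweep in 1:60) {
      for (i in seq_along(tnames)) {
        if (target_totals[i] == 0) { free[i] <- 0; next }
        lo <- 0; hi <- target_totals[i]
        for (it in 1:62) {
          mid <- (lo + hi) / 2
          free[i] <- mid
          w <- weight_at(free)
          bound <- protein_total *
            sum(w[!is.na(sp$target) & sp$target == tnames[i]]) / sum(w)
          if (mid + bound > target_totals[i]) hi <- mid else lo <- mid
        }
        free[i] <- (lo + hi) / 2
      }
      w <- weight_at(free)
      res <- vapply(seq_along(tnames), function(i) {
        if (target_totals[i] == 0) return(0)
        bound <- protein_total *
          sum(w[!is.na(sp$target) & sp$target == tnames[i]]) / sum(w)
        abs(free[i] + bound - target_totals[i]) / target_totals[i]
      }, 0)
      if (max(res) < 1e-12) break
    }
  }
  w <- weight_at(free)
  conc <- protein_total * w / sum(w)
  out <- sp
  out$concentration <- unname(conc)
  ns <- if (network$intact) 4 else 2
  attr(out, "saturation") <- if (protein_total > 0)
    sum(out$n_ca * out$concentration) / (ns * protein_total) else NA_real_
  attr(out, "free_targets") <- stats::setNames(free, tnames)
  attr(out, "ca_free") <- ca_free
  out
}

#' Saturation curve computed through the reaction network
#'
#' Convenience wrapper around [network_equilibrium()] over a calcium
#' grid; the independent oracle for the closed-form curves.
#'
#' @inheritParams network_equilibrium
#' @param ca_grid Calcium grid (molar).
#' @return A tibble with `ca_free_molar` and `saturation`.
#' @export
network_saturation_curve <- function(network, protein_total,
                                     target_totals = numeric(),
                                     ca_grid = default_ca_grid()) {
  tibble::tibble(
    ca_free_molar = ca_grid,
    saturation = vapply(ca_grid, function(ca) {
      attr(network_equilibrium(network, protein_total, target_totals, ca),
           "saturation")
    }, 0))
}

#' Intact-calmodulin target affinities from the standard assumptions
#'
#' Builds the four conformation-specific dissociation constants of a
#' whole-molecule target from three measurable quantities, using the
#' standard assignment rules: the RR affinity equals the affinity measured
#' at saturating calcium; the TT affinity equals the affinity measured
#' without calcium; the TR affinity (N lobe T, C-lobe R) equals the
#' affinity for the calcium-saturated isolated C-lobe; and the RT affinity
#' is taken roughly equal to the TT affinity.
#'
#' @param K_apo Affinity for calmodulin without calcium (molar).
#' @param K_ca_saturated Affinity at saturating calcium (molar).
#' @param K_TR2C_Rstate Affinity for the R state of the isolated C-lobe
#'   (molar).
#' @param name Target identifier.
#' @return An [intact_target_spec()].
#' @examples
#' assign_intact_target_affinities(600e-6, 0.1e-9, 735e-9, name = "WFF")
#' @export
assign_intact_target_affinities <- function(K_apo, K_ca_saturated,
                                            K_TR2C_Rstate, name = "target") {
  intact_target_spec(name,
                     K_RR = K_ca_saturated,
                     K_RT = K_apo,
                     K_TR = K_TR2C_Rstate,
                     K_TT = K_apo)
}

#' Stoichiometry matrix of a network
#'
#' Rows are species (protein states plus free calcium and free targets),
#' columns are reactions; entries are net stoichiometric coefficients of
#' the forward direction.
#'
#' @param network A [build_network()] result.
#' @return An integer matrix with dimnames.
#' @export
stoichiometry_matrix <- function(network) {
  re <- network$reactions
  tnames <- vapply(network$targets, function(t) t$name, "")
  rows <- c(network$species$id, "Ca", tnames)
  S <- matrix(0L, length(rows), nrow(re),
              dimnames = list(rows, re$id))
  for (i in seq_len(nrow(re))) {
    S[re$reactant[i], i] <- S[re$reactant[i], i] - 1L
    S[re$product[i], i] <- S[re$product[i], i] + 1L
    if (!is.na(re$ligand[i]))
      S[re$ligand[i], i] <- S[re$ligand[i], i] - 1L
  }
  S
}
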