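# Event-by-event electron transport.
#
# Electrons fly in straight lines through vacuum; optical depth accumulates
# only along chords through atom spheres, at a rate 1/lambda(kind, E) set by
# the owning molecule's material.  A free flight ends when the sampled
# exponential optical depth is exhausted inside a sphere (an interaction) or
# when the ray leaves the world box (escape).  Interactions follow the
# per-channel rules: elastic scattering (zero deposit, screened-Rutherford
# deflection), excitation (one permitted level, deposited locally),
# ionization (binding-energy deposit, one secondary, simplified Auger rule:
# C/O emit one Auger electron, N emits two), and DEA (full local deposit,
# electron terminated).  Every history closes an energy ledger:
# E_initial + E_auger_injected = E_deposited + E_escaped + E_cutoff_killed.

#' Isotropic cone source configuration
#'
#' @param energy beam energy, eV (monoenergetic).
#' @param position source point, nm.
#' @param axis unit vector from the source toward the targets.
#' @param half_angle cone half-angle, radians (0 gives a pencil beam);
#'   directions are drawn uniformly over the spherical cap.
#' @param n_histories number of primary electrons.
#' @return A `source_config`.
#' @export
source_config <- function(energy, position, axis, half_angle,
                          n_histories = 1L) {
  stopifnot(energy > 0, n_histories >= 0,
            half_angle >= 0, half_angle <= pi)
  structure(list(energy = energy, position = as.numeric(position),
                 axis = unitize(axis), half_angle = half_angle,
                 n_histories = as.integer(n_histories)),
            class = "source_config")
}

#' Place a source at a stand-off distance from a model
#'
#' Puts the point source on the +x side of the target bounding box, at
#' `distance` nm from the nearest box face, aimed at the box centre, with the
#' cone half-angle chosen to subtend the whole box (plus a 2% margin).
#'
#' @param model a `dna_model`.
#' @param energy beam energy, eV.
#' @param distance stand-off from the bounding box face, nm.
#' @param n_histories number of primaries.
#' @return A `source_config`.
#' @export
source_for_model <- function(model, energy, distance = 40,
                             n_histories = 1L) {
  lo <- model$extent["lo", ]; hi <- model$extent["hi", ]
  centre <- (lo + hi) / 2
  pos <- c(hi[1] + distance, centre[2], centre[3])
  axis <- unitize(centre - pos)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  vecs <- sweep(corners, 2, pos)
  cosang <- (vecs %*% axis) / sqrt(rowSums(vecs^2))
  half <- min(acos(pmin(pmax(cosang, -1), 1)) * 1.02 + 1e-6, pi)
  source_config(energy, pos, axis, max(half), n_histories)
}

#' Emit one primary electron
#'
#' Direction uniform over the configured cone, position at the source point,
#' energy exactly the beam energy.
#'
#' @param source a `source_config`.
#' @return List with `energy`, `position`, `direction`, `lineage`.
#' @export
emit_primary <- function(source) {
  ct0 <- cos(source$half_angle)
  ct <- 1 - runif(1) * (1 - ct0)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- runif(1, 0, 2 * pi)
  ob <- orthobasis(source$axis)
  dir <- ct * source$axis + st * (cos(phi) * ob$e1 + sin(phi) * ob$e2)
  list(energy = source$energy, position = source$position,
       direction = dir, lineage = "primary")
}

.isotropic_dir <- function() {
  ct <- runif(1, -1, 1)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- runif(1, 0, 2 * pi)
  c(st * cos(phi), st * sin(phi), ct)
}

# rotate `dir` by polar angle acos(ct) about itself, uniform azimuth
.deflect <- function(dir, ct) {
  st <- sqrt(max(0, 1 - ct^2))
  phi <- runif(1, 0, 2 * pi)
  ob <- orthobasis(dir)
  unitize(ct * dir + st * (cos(phi) * ob$e1 + sin(phi) * ob$e2))
}

# screened-Rutherford polar sampling; eta is the pinned energy-dependent
# screening parameter (swappable angular model)
.elastic_costheta <- function(E) {
  eta <- min(max(5 / E, 1e-3), 10)
  u <- runif(1)
  1 - 2 * eta * u / (1 + eta - u)
}

#' Build a tracking context
#'
#' Bundles everything the transport loop needs: the spatial index over the
#' atom spheres, per-atom lookups (molecule kind, molecule id, element), the
#' cross-section library with a per-energy cache of channel cross-sections
#' and inverse mean free paths, the world box and the tracking cutoff.
#'
#' @param model a `dna_model`.
#' @param library an `xsec_library` (default fixture library).
#' @param world_edge edge of the cubic vacuum world box, nm (centred on the
#'   scene).
#' @param cell_size spatial-index cell, nm.
#' @param cutoff tracking cutoff, eV; electrons below it are killed with a
#'   local deposit booked as `cutoff_killed`.
#' @return A `tracking_context`.
#' @export
tracking_context <- function(model, library = default_xsec_library(),
                             world_edge = 400, cell_size = 1.0,
                             cutoff = 1.0) {
  validate_dna_model(model)
  idx <- build_spatial_index(model, cell_size)
  mol <- model$molecules
  kind_of_mol <- setNames(match(mol$kind, MOLECULE_KINDS), mol$molecule_id)
  centre <- (model$extent["lo", ] + model$extent["hi", ]) / 2
  ctx <- new.env(parent = emptyenv())
  ctx$model <- model
  ctx$library <- library
  ctx$index <- idx
  ctx$atom_kind <- unname(kind_of_mol[as.character(model$atoms$molecule_id)])
  ctx$atom_mol <- model$atoms$molecule_id
  ctx$atom_elem <- model$atoms$element
  ctx$mol_kind <- mol$kind[order(mol$molecule_id)]
  ctx$mol_group <- mol$group[order(mol$molecule_id)]
  ctx$mol_strand <- mol$strand[order(mol$molecule_id)]
  ctx$mol_bp <- mol$bp_index[order(mol$molecule_id)]
  ctx$mol_target <- mol$target[order(mol$molecule_id)]
  ctx$world_lo <- centre - world_edge / 2
  ctx$world_hi <- centre + world_edge / 2
  ctx$cutoff <- cutoff
  ctx$ecache <- new.env(parent = emptyenv())
  class(ctx) <- "tracking_context"
  ctx
}

# per-energy physics: 4-channel sigma matrix (kind x channel) and inverse
# mean free paths per kind; memoized because electron energies recur
.kind_physics <- function(ctx, E) {
  key <- sprintf("%.10g", E)
  hit <- ctx$ecache[[key]]
  if (!is.null(hit)) return(hit)
  lib <- ctx$library
  sig <- t(vapply(MOLECULE_KINDS,
                  function(k) vapply(lib$tables[[k]], sigma, 0, E = E),
                  numeric(length(SAMPLING_CHANNELS))))
  tot <- rowSums(sig)
  invl <- unname(lib$number_density_nm3[MOLECULE_KINDS] * tot)
  out <- list(sig = sig, inv_lambda = invl)
  ctx$ecache[[key]] <- out
  out
}

#' Free flight of one electron through the scene
#'
#' Samples an exponential number of mean free paths and advances the electron
#' along its ray, accumulating optical depth only inside atom spheres (chord
#' length over lambda of the owning molecule's kind; vacuum contributes
#' zero).  Returns either an interaction site or an escape through the world
#' box.
#'
#' @param position,direction,energy electron state (nm, unit vector, eV).
#' @param ctx a `tracking_context`.
#' @return A list: either `type = "interaction"` with the hit atom index,
#'   position and its molecule annotation, or `type = "escape"`.
#' @export
fly <- function(position, direction, energy, ctx) {
  t_box <- aabb_exit(position, direction, ctx$world_lo, ctx$world_hi)
  hits <- cpp_ray_trace(.index_ptr(ctx$index), position, direction, t_box)
  if (nrow(hits) == 0) return(list(type = "escape"))

  phys <- .kind_physics(ctx, energy)
  akind <- ctx$atom_kind[hits[, 1]]
  invl <- phys$inv_lambda[akind]
  tau <- (hits[, 3] - hits[, 2]) * invl
  cum <- cumsum(tau)
  total <- cum[length(cum)]
  u <- rexp(1)
  if (!(total > 0) || u > total) return(list(type = "escape"))

  i <- which(cum >= u)[1]
  before <- if (i > 1) cum[i - 1] else 0
  t_star <- hits[i, 2] + (u - before) / invl[i]
  atom <- as.integer(hits[i, 1])
  list(type = "interaction", atom = atom,
       position = position + t_star * direction,
       kind_idx = akind[i], sig = phys$sig[akind[i], ],
       molecule_id = ctx$atom_mol[atom], element = ctx$atom_elem[atom])
}

#' Realize one interaction
#'
#' Applies the per-channel physics at an interaction site and returns the
#' energy deposit, the surviving electron (if any) and secondaries.
#' Channels: `elastic` deposits nothing and resamples the direction;
#' `excitation` picks one permitted level (uniformly among vibrational and
#' electronic levels not exceeding the electron energy) and deposits it --
#' the event is recorded as vibrational or electronic excitation according to
#' the realized level; `ionization` deposits the binding energy, spawns a
#' secondary with kinetic energy uniform on (0, (E-B)/2] plus the
#' element-dependent Auger electrons; `dea` deposits the electron's entire
#' remaining energy and terminates it.
#'
#' @param energy,direction electron state before the interaction.
#' @param channel sampling channel (`elastic`, `excitation`, `ionization`,
#'   `dea`).
#' @param kind molecule kind at the site.
#' @param element element of the struck atom (drives the Auger rule).
#' @param library an `xsec_library`.
#' @return List: `channel` (event channel after level realization),
#'   `deposit` (eV), `energy`/`direction` of the survivor, `dead` flag,
#'   `secondaries` (list of `energy`/`lineage`), `auger_injected` (eV).
#' @export
do_interaction <- function(energy, direction, channel, kind, element,
                           library) {
  secondaries <- list()
  auger_injected <- 0
  switch(channel,
    elastic = {
      list(channel = "elastic", deposit = 0, energy = energy,
           direction = .deflect(direction, .elastic_costheta(energy)),
           dead = FALSE, secondaries = secondaries, auger_injected = 0)
    },
    excitation = {
      lv <- library$levels[[kind]]
      permitted <- c(lv$vibrational, lv$electronic)
      permitted <- permitted[permitted <= energy]
      if (!length(permitted)) stop("excitation sampled below every level")
      n_vib <- sum(lv$vibrational <= energy)
      pick <- sample.int(length(permitted), 1L)
      L <- permitted[pick]
      list(channel = if (pick <= n_vib) "vibrational_excitation"
                     else "electronic_excitation",
           deposit = L, energy = energy - L, direction = direction,
           dead = FALSE, secondaries = secondaries, auger_injected = 0)
    },
    ionization = {
      B <- library$binding[[kind]]
      if (energy <= B) stop("ionization sampled below the binding energy")
      eps <- runif(1, 0, (energy - B) / 2)
      secondaries[[1]] <- list(energy = eps, lineage = "ionization_secondary")
      mult <- library$auger_multiplicity[element]
      if (!is.na(mult) && mult > 0) {
        ea <- library$auger_energy_ev[[element]]
        for (j in seq_len(mult)) {
          secondaries[[length(secondaries) + 1L]] <-
            list(energy = ea, lineage = "auger")
          auger_injected <- auger_injected + ea
        }
      }
      list(channel = "ionization", deposit = B, energy = energy - B - eps,
           direction = direction, dead = FALSE, secondaries = secondaries,
           auger_injected = auger_injected)
    },
    dea = {
      list(channel = "dea", deposit = energy, energy = 0, direction = NULL,
           dead = TRUE, secondaries = secondaries, auger_injected = 0)
    },
    stop("unknown channel: ", channel))
}

# --- event collection -------------------------------------------------------

new_event_collector <- function() {
  col <- new.env(parent = emptyenv())
  col$n <- 0L
  col$cap <- 256L
  for (f in c("history_id", "strand", "bp_index", "target", "molecule_id"))
    col[[f]] <- integer(256L)
  for (f in c("x", "y", "z", "deposit_ev"))
    col[[f]] <- numeric(256L)
  for (f in c("lineage", "channel", "kind", "group", "element"))
    col[[f]] <- character(256L)
  col
}

.col_fields <- c("history_id", "lineage", "channel", "kind", "group",
                 "strand", "bp_index", "target", "molecule_id",
                 "x", "y", "z", "deposit_ev", "element")

add_event <- function(col, history_id, lineage, channel, kind, group,
                      strand, bp_index, target, molecule_id, pos,
                      deposit, element) {
  n <- col$n + 1L
  if (n > col$cap) {
    for (f in .col_fields) {
      v <- col[[f]]
      length(v) <- col$cap * 2L
      col[[f]] <- v
    }
    col$cap <- col$cap * 2L
  }
  col$history_id[n] <- history_id; col$lineage[n] <- lineage
  col$channel[n] <- channel; col$kind[n] <- kind; col$group[n] <- group
  col$strand[n] <- strand; col$bp_index[n] <- bp_index
  col$target[n] <- target; col$molecule_id[n] <- molecule_id
  col$x[n] <- pos[1]; col$y[n] <- pos[2]; col$z[n] <- pos[3]
  col$deposit_ev[n] <- deposit; col$element[n] <- element
  col$n <- n
  invisible(col)
}

collector_events <- function(col) {
  n <- col$n
  out <- data.table(
    history_id = col$history_id[seq_len(n)],
    lineage = col$lineage[seq_len(n)],
    channel = col$channel[seq_len(n)],
    kind = col$kind[seq_len(n)],
    group = col$group[seq_len(n)],
    strand = col$strand[seq_len(n)],
    bp_index = col$bp_index[seq_len(n)],
    target = col$target[seq_len(n)],
    molecule_id = col$molecule_id[seq_len(n)],
    x = col$x[seq_len(n)], y = col$y[seq_len(n)], z = col$z[seq_len(n)],
    deposit_ev = col$deposit_ev[seq_len(n)],
    element = col$element[seq_len(n)])
  out
}

# --- history and simulation loops ------------------------------------------

#' Track one primary electron and all of its descendants
#'
#' Stack-based processing of the primary, ionization secondaries and Auger
#' electrons until each escapes, is terminated by DEA, or falls below the
#' tracking cutoff (its remaining energy is deposited locally and booked as
#' `cutoff_killed`).
#'
#' @param primary list with `energy`, `position`, `direction` (e.g. from
#'   [emit_primary()]).
#' @param ctx a `tracking_context`.
#' @param collector an event collector (internal); when `NULL` a fresh one is
#'   used and the events are returned as a table.
#' @param history_id integer label written into the events.
#' @return List with the per-history energy ledger (`E_initial`, `E_auger`,
#'   `E_deposited`, `E_escaped`, `E_cutoff`) and, when `collector` was NULL,
#'   the event table.
#' @export
run_history <- function(primary, ctx, collector = NULL, history_id = 1L) {
  own <- is.null(collector)
  if (own) collector <- new_event_collector()
  E_initial <- primary$energy
  E_auger <- 0; E_dep <- 0; E_esc <- 0; E_cut <- 0
  cutoff <- ctx$cutoff
  lib <- ctx$library

  stack <- list(list(energy = primary$energy, position = primary$position,
                     direction = primary$direction, lineage = "primary"))
  while (length(stack)) {
    el <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    repeat {
      if (el$energy < cutoff) {
        E_cut <- E_cut + el$energy
        break
      }
      fl <- fly(el$position, el$direction, el$energy, ctx)
      if (fl$type == "escape") {
        E_esc <- E_esc + el$energy
        break
      }
      ch <- sample_interaction_type(fl$sig)
      kind <- MOLECULE_KINDS[fl$kind_idx]
      res <- do_interaction(el$energy, el$direction, ch, kind, fl$element,
                            lib)
      mid <- fl$molecule_id
      add_event(collector, history_id, el$lineage, res$channel, kind,
                ctx$mol_group[mid], ctx$mol_strand[mid], ctx$mol_bp[mid],
                ctx$mol_target[mid], mid, fl$position, res$deposit,
                fl$element)
      E_dep <- E_dep + res$deposit
      E_auger <- E_auger + res$auger_injected
      for (s in res$secondaries) {
        stack[[length(stack) + 1L]] <-
          list(energy = s$energy, position = fl$position,
               direction = .isotropic_dir(), lineage = s$lineage)
      }
      if (res$dead) break
      el$energy <- res$energy
      el$position <- fl$position
      el$direction <- res$direction
    }
  }
  ledger <- c(E_initial = E_initial, E_auger = E_auger, E_deposited = E_dep,
              E_escaped = E_esc, E_cutoff = E_cut)
  if (own) list(ledger = ledger, events = collector_events(collector))
  else list(ledger = ledger)
}

#' Run a full simulation at one beam energy
#'
#' `n_histories` independent histories; each history uses its own RNG
#' substream derived from the master seed by a counter scheme, so the run is
#' reproducible as a whole and per history.
#'
#' @param ctx a `tracking_context`.
#' @param source a `source_config` (its `n_histories` is used unless
#'   overridden).
#' @param seed master seed (integer).
#' @param n_histories optional override of `source$n_histories`.
#' @return A `simulation_result`: event table, per-history ledger table,
#'   `energy`, `n_histories`, `seed`.
#' @export
run_simulation <- function(ctx, source, seed = 1L, n_histories = NULL) {
  n <- as.integer(n_histories %||% source$n_histories)
  col <- new_event_collector()
  led <- matrix(0, n, 5,
                dimnames = list(NULL, c("E_initial", "E_auger",
                                        "E_deposited", "E_escaped",
                                        "E_cutoff")))
  for (h in seq_len(n)) {
    set.seed(derive_seed(seed, h))
    pr <- emit_primary(source)
    res <- run_history(pr, ctx, collector = col, history_id = h)
    led[h, ] <- res$ledger
  }
  structure(list(events = collector_events(col),
                 ledger = as.data.table(led),
                 energy = source$energy, n_histories = n, seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %g eV beam, %d histories, %d events, seed %d\n",
    x$energy, x$n_histories, nrow(x$events), x$seed))
  invisible(x)
}

#' Check the per-history energy ledger balance
#'
#' @param sim a `simulation_result`.
#' @return Maximum relative imbalance of
#'   `E_initial + E_auger - (E_deposited + E_escaped + E_cutoff)` over the
#'   histories.
#' @export
ledger_imbalance <- function(sim) {
  l <- sim$ledger
  num <- abs(l$E_initial + l$E_auger -
               (l$E_deposited + l$E_escaped + l$E_cutoff))
  den <- pmax(l$E_initial + l$E_auger, .Machine$double.eps)
  max(num / den)
}
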