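#' A single tumour cell
#'
#' Constructs the per-cell record used by the scalar cell-dynamics
#' operations: state (`P` proliferative, `Q` quiescent, `A` apoptotic, `N`
#' necrotic), cycle duration `mu`, current phase (G1, S, G2, M) and the
#' time already spent in it. Phase durations are `G1 = mu - (S+G2+M)` with
#' the S, G2 and M durations fixed by the parameter set; only the G1 share
#' varies between cells.
#'
#' @param state one of `"P"`, `"Q"`, `"A"`, `"N"`.
#' @param mu cycle duration, h.
#' @param phase one of `"G1"`, `"S"`, `"G2"`, `"M"`.
#' @param phase_clock h elapsed in the current phase.
#' @param params a [model_params()] object.
#' @return a list of class `vt_cell`.
#' @export
vt_cell <- function(state = "P", mu = 24, phase = "G1", phase_clock = 0,
                    params = model_params()) {
  stopifnot(state %in% c("P", "Q", "A", "N"),
            phase %in% c("G1", "S", "G2", "M"), mu > 0, phase_clock >= 0)
  durs <- c(G1 = mu - (params$S_dur + params$G2_dur + params$M_dur),
            S = params$S_dur, G2 = params$G2_dur, M = params$M_dur)
  if (durs[["G1"]] <= 0)
    stop("mu must exceed the fixed S+G2+M phase time", call. = FALSE)
  if (phase_clock > durs[[phase]])
    stop("phase_clock exceeds the duration of phase ", phase, call. = FALSE)
  structure(list(state = state, mu = mu, phase = phase,
                 phase_clock = phase_clock, phase_durations = durs,
                 division_ready = FALSE),
            class = "vt_cell")
}

#' Oxygen-driven cell-state transitions
#'
#' Applies the state machine of the automaton to one cell given its local
#' oxygen concentration (normalized units): a proliferative cell arrests
#' (P to Q) only if oxygen falls below the quiescence threshold *while the
#' cell is in G1*, its oxygen-sensitive phase; a quiescent cell reverts to
#' P as soon as oxygen is back at or above the threshold; any living cell
#' necroses if oxygen falls below the necrosis threshold. Dead states are
#' absorbing: a dead cell is returned unchanged (with a message).
#'
#' @param cell a [vt_cell()].
#' @param O_local local oxygen concentration, normalized units.
#' @param params a [model_params()] object.
#' @return the updated cell.
#' @export
update_cell_state <- function(cell, O_local, params = model_params()) {
  stopifnot(inherits(cell, "vt_cell"), O_local >= 0)
  if (cell$state %in% c("A", "N")) {
    message("update_cell_state: dead cell passed; no-op")
    return(cell)
  }
  if (O_local < params$O_necrosis) {
    cell$state <- "N"
  } else if (cell$state == "P" && cell$phase == "G1" &&
             O_local < params$O_quiescence) {
    cell$state <- "Q"
  } else if (cell$state == "Q" && O_local >= params$O_quiescence) {
    cell$state <- "P"
  }
  cell
}

#' Draw the cycle duration of a daughter cell
#'
#' The daughter's cycle duration is drawn from a Gaussian centred on the
#' mother's duration with standard deviation `sigma`, truncated to
#' `[mu - 3 sigma, mu + 3 sigma]`. Only the G1 phase absorbs the change;
#' the S, G2 and M durations are inherited unchanged.
#'
#' @param mu_mother mother-cell cycle duration, h (> 0).
#' @param sigma standard deviation, h (>= 0).
#' @param n number of draws.
#' @return numeric vector of `n` cycle durations (h). Uses the R RNG.
#' @export
draw_daughter_cycle <- function(mu_mother, sigma, n = 1L) {
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be non-negative", call. = FALSE)
  stopifnot(mu_mother > 0)
  if (sigma == 0) return(rep(mu_mother, n))
  x <- stats::rnorm(n, mu_mother, sigma)
  bad <- which(abs(x - mu_mother) > 3 * sigma)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu_mother, sigma)
    bad <- bad[abs(x[bad] - mu_mother) > 3 * sigma]
  }
  x
}

#' Advance the cell cycle
#'
#' Proliferative cells accumulate phase time and roll over through
#' G1, S, G2 and M; completing M flags the cell division-ready (the clock
#' then holds until a division attempt succeeds). Quiescent and dead cells
#' do not progress.
#'
#' @param cell a [vt_cell()].
#' @param dt time increment, h (> 0).
#' @param O_local local oxygen (unused by progression itself; state
#'   changes are the job of [update_cell_state()]).
#' @return the updated cell.
#' @export
advance_cycle <- function(cell, dt, O_local = NULL) {
  stopifnot(inherits(cell, "vt_cell"), dt > 0)
  if (cell$state != "P" || cell$division_ready) return(cell)
  phases <- c("G1", "S", "G2", "M")
  k <- match(cell$phase, phases)
  clock <- cell$phase_clock + dt
  while (clock >= cell$phase_durations[[k]]) {
    clock <- clock - cell$phase_durations[[k]]
    if (k == 4L) {
      cell$division_ready <- TRUE
      clock <- 0
      break
    }
    k <- k + 1L
  }
  cell$phase <- phases[k]
  cell$phase_clock <- clock
  cell
}

#' Space-constrained cell division
#'
#' Attempts to divide the division-ready proliferative cell at `(i, j)`:
#' \enumerate{
#' \item if at least one of its 8 Moore neighbours is free, the daughter
#'   is placed in a uniformly chosen free neighbour;
#' \item otherwise, if some occupied neighbour can itself be pushed into a
#'   free element of *its* Moore neighbourhood (one displacement step,
#'   beyond the first occupied row), a uniformly chosen such
#'   (neighbour, free element) pair is used: the neighbour moves outward
#'   and the daughter takes its vacated element;
#' \item otherwise no placement is possible; if `commit_apoptosis` is
#'   `TRUE` the mother enters apoptosis, else the outcome is reported as
#'   `"blocked"` (the driver lets a blocked cell retry for a bounded time
#'   before committing it).
#' }
#' On success the daughter starts in G1 with a cycle duration drawn by
#' [draw_daughter_cycle()], and the mother's cycle restarts.
#'
#' @param grid a `sim_grid`.
#' @param i,j coordinates of the dividing cell.
#' @param commit_apoptosis logical, see above.
#' @return a list with `outcome` (`"placed"`, `"pushed"`, `"apoptosis"` or
#'   `"blocked"`), `daughter` (coordinates or `NULL`) and `moved`
#'   (`list(from, to)` for a push, else `NULL`). Uses the R RNG.
#' @export
attempt_division <- function(grid, i, j, commit_apoptosis = TRUE) {
  if (grid$occ[i, j] != STATE_P || !grid$ready[i, j])
    stop("attempt_division called on a cell that is not division-ready P",
         call. = FALSE)
  nb <- neighbours8(i, j, grid$n)
  free <- grid$occ[nb] == STATE_EMPTY
  if (any(free)) {
    pick <- nb[sample_one(which(free)), , drop = FALSE]
    finish_division(grid, i, j, pick[1], pick[2])
    return(list(outcome = "placed", daughter = c(pick[1], pick[2]),
                moved = NULL))
  }
  ## all first-ring neighbours occupied: look for a one-step push
  pairs_from <- NULL; pairs_to <- NULL
  for (r in seq_len(nrow(nb))) {
    nb2 <- neighbours8(nb[r, 1], nb[r, 2], grid$n)
    f2 <- nb2[grid$occ[nb2] == STATE_EMPTY, , drop = FALSE]
    if (nrow(f2)) {
      pairs_from <- rbind(pairs_from, nb[rep(r, nrow(f2)), , drop = FALSE])
      pairs_to <- rbind(pairs_to, f2)
    }
  }
  if (!is.null(pairs_from) && nrow(pairs_from)) {
    r <- sample_one(seq_len(nrow(pairs_from)))
    from <- pairs_from[r, ]; to <- pairs_to[r, ]
    move_occupant(grid, from[1], from[2], to[1], to[2])
    finish_division(grid, i, j, from[1], from[2])
    return(list(outcome = "pushed", daughter = c(from[1], from[2]),
                moved = list(from = from, to = to)))
  }
  if (commit_apoptosis) {
    grid$occ[i, j] <- STATE_A
    grid$death_time[i, j] <- grid$time
    grid$ready[i, j] <- FALSE
    grid$n_apoptosis <- grid$n_apoptosis + 1L
    return(list(outcome = "apoptosis", daughter = NULL, moved = NULL))
  }
  list(outcome = "blocked", daughter = NULL, moved = NULL)
}

## uniform choice that does not fall into sample()'s scalar trap
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

## copy every per-cell attribute from one element to another (push step).
## Writes go through the in-place setters: these per-cell updates run
## thousands of times per step and R's copy-on-write would duplicate the
## full state matrices once their reference counts saturate.
move_occupant <- function(grid, fi, fj, ti, tj) {
  n <- grid$n
  f <- (fj - 1L) * n + fi
  t <- (tj - 1L) * n + ti
  cpp_set_int(grid$occ, t, grid$occ[f])
  cpp_set_num(grid$mu, t, grid$mu[f])
  cpp_set_num(grid$g1, t, grid$g1[f])
  cpp_set_int(grid$phase, t, grid$phase[f])
  cpp_set_num(grid$clock, t, grid$clock[f])
  cpp_set_lgl(grid$ready, t, grid$ready[f])
  cpp_set_num(grid$ready_since, t, grid$ready_since[f])
  cpp_set_num(grid$death_time, t, grid$death_time[f])
  cpp_set_int(grid$occ, f, STATE_EMPTY)
  cpp_set_lgl(grid$ready, f, FALSE)
  invisible(grid)
}

## place the daughter and restart the mother's cycle
finish_division <- function(grid, mi, mj, di, dj) {
  p <- grid$params
  n <- grid$n
  fixed <- p$S_dur + p$G2_dur + p$M_dur
  m <- (mj - 1L) * n + mi
  d <- (dj - 1L) * n + di
  mu_d <- max(fixed + 0.1,
              draw_daughter_cycle(grid$mu[m], p$sigma_cycle))
  cpp_set_int(grid$occ, d, STATE_P)
  cpp_set_num(grid$mu, d, mu_d)
  cpp_set_num(grid$g1, d, mu_d - fixed)
  cpp_set_int(grid$phase, c(d, m), 1L)
  cpp_set_num(grid$clock, c(d, m), 0)
  cpp_set_lgl(grid$ready, c(d, m), FALSE)
  grid$n_divisions <- grid$n_divisions + 1L
  invisible(grid)
}

## ---- vectorized lattice versions used by the driver ---------------------

## oxygen-driven state transitions for every living cell on the grid
update_states_all <- function(grid) {
  p <- grid$params
  occ <- grid$occ
  living <- occ == STATE_P | occ == STATE_Q
  necrose <- living & grid$O < p$O_necrosis
  if (any(necrose)) {
    grid$occ[necrose] <- STATE_N
    grid$death_time[necrose] <- grid$time
    grid$ready[necrose] <- FALSE
    grid$n_necrosis <- grid$n_necrosis + sum(necrose)
  }
  occ <- grid$occ
  arrest <- occ == STATE_P & grid$phase == 1L & grid$O < p$O_quiescence
  revert <- occ == STATE_Q & grid$O >= p$O_quiescence
  grid$occ[arrest] <- STATE_Q
  grid$ready[arrest] <- FALSE
  grid$occ[revert] <- STATE_P
  invisible(grid)
}

## cycle progression for every P cell (Q/A/N cells are arrested)
advance_cycle_all <- function(grid, dt) {
  p <- grid$params
  durs2 <- p$S_dur; durs3 <- p$G2_dur; durs4 <- p$M_dur
  idx <- which(grid$occ == STATE_P & !grid$ready)
  if (!length(idx)) return(invisible(grid))
  clock <- grid$clock[idx] + dt
  phase <- grid$phase[idx]
  g1 <- grid$g1[idx]
  ready <- logical(length(idx))
  repeat {
    dur <- ifelse(phase == 1L, g1,
           ifelse(phase == 2L, durs2, ifelse(phase == 3L, durs3, durs4)))
    roll <- !ready & clock >= dur
    if (!any(roll)) break
    clock[roll] <- clock[roll] - dur[roll]
    done <- roll & phase == 4L
    ready[done] <- TRUE
    clock[done] <- 0
    phase[roll & !done] <- phase[roll & !done] + 1L
  }
  grid$clock[idx] <- clock
  grid$phase[idx] <- phase
  new_ready <- idx[ready]
  grid$ready[new_ready] <- TRUE
  grid$ready_since[new_ready] <- grid$time
  invisible(grid)
}

## number of free Moore neighbours of every element (boundary-clipped)
free_neighbour_counts <- function(occ) {
  n1 <- nrow(occ); n2 <- ncol(occ)
  free01 <- (occ == STATE_EMPTY) * 1L
  cnt <- matrix(0L, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ri <- max(1, 1 + di):min(n1, n1 + di)
    rj <- max(1, 1 + dj):min(n2, n2 + dj)
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(n2, n2 - dj)
    cnt[ri, rj] <- cnt[ri, rj] + free01[si, sj]
  }
  cnt
}

## division sweep: every division-ready P cell attempts in random order;
## cells blocked longer than division_wait commit to apoptosis.
## A free-neighbour-count map (computed once per sweep) short-circuits
## hopelessly boxed-in cells: space is only ever consumed during a sweep,
## never created, so a cell whose whole two-ring neighbourhood starts the
## sweep full stays blocked for the whole sweep.
division_sweep <- function(grid) {
  ready <- grid$occ == STATE_P & grid$ready
  if (!any(ready)) return(invisible(grid))
  n <- grid$n
  fc <- free_neighbour_counts(grid$occ)
  ## hopeless cells (entire two-ring neighbourhood full at sweep start)
  ## are handled vectorized: overdue ones commit to apoptosis, the rest
  ## just wait -- no free element can appear during the sweep
  fcmax <- matrix(0L, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ri <- max(1, 1 + di):min(n, n + di)
    rj <- max(1, 1 + dj):min(n, n + dj)
    si <- max(1, 1 - di):min(n, n - di)
    sj <- max(1, 1 - dj):min(n, n - dj)
    fcmax[ri, rj] <- pmax(fcmax[ri, rj], fc[si, sj])
  }
  hopeless <- ready & fc == 0L & fcmax == 0L
  if (any(hopeless)) {
    overdue_h <- hopeless &
      grid$time - grid$ready_since >= grid$params$division_wait
    if (any(overdue_h)) {
      grid$occ[overdue_h] <- STATE_A
      grid$death_time[overdue_h] <- grid$time
      grid$ready[overdue_h] <- FALSE
      grid$n_apoptosis <- grid$n_apoptosis + sum(overdue_h)
    }
    ready <- ready & !hopeless
  }
  idx <- which(ready)
  if (!length(idx)) return(invisible(grid))
  idx <- if (length(idx) > 1L) idx[sample.int(length(idx))] else idx
  offs <- c(-1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
  p <- grid$params
  fixed <- p$S_dur + p$G2_dur + p$M_dur
  for (e in idx) {
    if (grid$occ[e] != STATE_P || !grid$ready[e]) next # displaced meanwhile
    i <- (e - 1L) %% n + 1L
    j <- (e - 1L) %/% n + 1L
    overdue <- grid$time - grid$ready_since[e] >= p$division_wait
    interior <- i > 1L && i < n && j > 1L && j < n
    if (fc[e] == 0L) {
      ## no free first-ring element at sweep start; a push needs a free
      ## element in some neighbour's own neighbourhood
      nb_fc <- if (interior) fc[e + offs] else fc[neighbours8(i, j, n)]
      if (all(nb_fc == 0L)) {
        if (overdue) {
          cpp_set_int(grid$occ, e, STATE_A)
          cpp_set_num(grid$death_time, e, grid$time)
          cpp_set_lgl(grid$ready, e, FALSE)
          grid$n_apoptosis <- grid$n_apoptosis + 1L
        }
        next
      }
      ## inline push for cells two elements clear of the border: every
      ## (occupied neighbour, free second-ring element) pair, uniform
      if (i > 2L && i < n - 1L && j > 2L && j < n - 1L) {
        nb <- e + offs
        if (all(grid$occ[nb] != STATE_EMPTY)) {
          nb2 <- rep(nb, each = 8L) + offs      # 64 candidate targets
          ok <- grid$occ[nb2] == STATE_EMPTY & nb2 != e
          if (any(ok)) {
            pick <- which(ok)
            r <- if (length(pick) == 1L) pick else
              pick[sample.int(length(pick), 1L)]
            from <- nb[(r - 1L) %/% 8L + 1L]
            to <- nb2[r]
            fi <- (from - 1L) %% n + 1L; fj <- (from - 1L) %/% n + 1L
            ti <- (to - 1L) %% n + 1L; tj <- (to - 1L) %/% n + 1L
            move_occupant(grid, fi, fj, ti, tj)
            finish_division(grid, i, j, fi, fj)
            next
          }
          if (overdue) {
            cpp_set_int(grid$occ, e, STATE_A)
            cpp_set_num(grid$death_time, e, grid$time)
            cpp_set_lgl(grid$ready, e, FALSE)
            grid$n_apoptosis <- grid$n_apoptosis + 1L
          }
          next
        }
      }
      attempt_division(grid, i, j, commit_apoptosis = overdue)
      next
    }
    ## fast path for the common case: an interior cell with free space
    if (interior) {
      nb <- e + offs
      free <- nb[grid$occ[nb] == STATE_EMPTY]
      if (length(free)) {
        d <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
        mu_d <- max(fixed + 0.1, draw_daughter_cycle(grid$mu[e], p$sigma_cycle))
        cpp_set_int(grid$occ, d, STATE_P)
        cpp_set_num(grid$mu, d, mu_d)
        cpp_set_num(grid$g1, d, mu_d - fixed)
        cpp_set_int(grid$phase, c(d, e), 1L)
        cpp_set_num(grid$clock, c(d, e), 0)
        cpp_set_lgl(grid$ready, c(d, e), FALSE)
        grid$n_divisions <- grid$n_divisions + 1L
        next
      }
    }
    attempt_division(grid, i, j, commit_apoptosis = overdue)
  }
  invisible(grid)
}

## free the elements of dead cells whose lysis delay has elapsed
lysis_sweep <- function(grid) {
  dead <- (grid$occ == STATE_A | grid$occ == STATE_N) &
    grid$time - grid$death_time >= grid$params$lysis_delay
  if (any(dead)) {
    grid$occ[dead] <- STATE_EMPTY
    grid$n_lysed <- grid$n_lysed + sum(dead)
  }
  invisible(grid)
}
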