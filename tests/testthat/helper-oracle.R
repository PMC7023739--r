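# Independent reference scheduler for small deterministic instances.
#
# Three-phase (activity-scanning) simulation: advance the clock to the next
# completion, process all completions due, then repeatedly allocate free
# resources to waiting women in FIFO (queue-entry time, woman id) order
# until no allocation is possible. Structurally different from the
# package's event-calendar engine; intended for instances whose service
# durations are pairwise distinct so that no two completions coincide.
#
# Returns a matrix with the same wait/departure columns as the engine.

oracle_day <- function(arrivals_at, order_doc, n_rec, n_mid, n_doc, n_ctg,
                       svc, checks) {
  n <- length(arrivals_at)
  free <- c(rec = n_rec, mid = n_mid, doc = n_doc, ctg = n_ctg)

  # phase: "pending" (arrival not yet happened), "waiting", "service", "done"
  phase <- rep("pending", n)
  until <- arrivals_at          # next transition time for pending/service
  cur <- rep("", n)             # current service activity
  queue <- rep("", n)           # queue currently waited in
  q_enter <- rep(NA_real_, n)
  doctor_first <- rep(FALSE, n)
  held <- rep(FALSE, n)
  ctg_done <- rep(FALSE, n)

  wait <- matrix(0, n, 6,
                 dimnames = list(NULL, c("checkin", "machine", "connect",
                                         "disconnect", "doctor", "checkout")))
  dep <- rep(NA_real_, n)

  join <- function(w, qname, t) {
    phase[w] <<- "waiting"
    queue[w] <<- qname
    q_enter[w] <<- t
  }
  start <- function(w, act, dur, t) {
    phase[w] <<- "service"
    cur[w] <<- act
    until[w] <<- t + dur
  }

  complete <- function(w, t) {
    act <- cur[w]
    if (act == "checkin") {
      free["rec"] <<- free["rec"] + 1
      if (order_doc && free["doc"] > 0) {
        doctor_first[w] <<- TRUE
        free["doc"] <<- free["doc"] - 1
        start(w, "consult", svc[w, 5], t)
      } else {
        join(w, "ctg", t)
      }
    } else if (act == "consult") {
      free["doc"] <<- free["doc"] + 1
      if (doctor_first[w] && !ctg_done[w]) join(w, "ctg", t)
      else join(w, "checkout_q", t)
    } else if (act == "connect") {
      if (checks[w] >= 5) held[w] <<- TRUE
      else free["mid"] <<- free["mid"] + 1
      start(w, "scan", svc[w, 3], t)
    } else if (act == "scan") {
      if (held[w]) start(w, "disconnect", svc[w, 4], t)
      else join(w, "mid_disc", t)
    } else if (act == "disconnect") {
      free["mid"] <<- free["mid"] + 1
      free["ctg"] <<- free["ctg"] + 1
      ctg_done[w] <<- TRUE
      if (doctor_first[w]) join(w, "checkout_q", t)
      else join(w, "doc", t)
    } else if (act == "checkout") {
      free["rec"] <<- free["rec"] + 1
      dep[w] <<- t
      phase[w] <<- "done"
    }
  }

  allocate <- function(t) {
    repeat {
      progressed <- FALSE
      pick <- function(qname) {
        cand <- which(phase == "waiting" & queue == qname)
        if (length(cand) == 0) return(NA_integer_)
        cand[order(q_enter[cand], cand)][1]
      }
      while (free["rec"] > 0 &&
             !is.na(w <- pick_first(phase, queue, q_enter,
                                    c("checkin_q", "checkout_q")))) {
        free["rec"] <<- free["rec"] - 1
        if (queue[w] == "checkin_q") {
          wait[w, "checkin"] <<- t - q_enter[w]
          start(w, "checkin", svc[w, 1], t)
        } else {
          wait[w, "checkout"] <<- t - q_enter[w]
          start(w, "checkout", svc[w, 6], t)
        }
        progressed <- TRUE
      }
      while (free["ctg"] > 0 && !is.na(w <- pick("ctg"))) {
        free["ctg"] <<- free["ctg"] - 1
        wait[w, "machine"] <<- t - q_enter[w]
        join(w, "mid_conn", t)
        progressed <- TRUE
      }
      while (free["mid"] > 0 &&
             !is.na(w <- pick_first(phase, queue, q_enter,
                                    c("mid_conn", "mid_disc")))) {
        free["mid"] <<- free["mid"] - 1
        if (queue[w] == "mid_conn") {
          wait[w, "connect"] <<- t - q_enter[w]
          start(w, "connect", svc[w, 2], t)
        } else {
          wait[w, "disconnect"] <<- t - q_enter[w]
          start(w, "disconnect", svc[w, 4], t)
        }
        progressed <- TRUE
      }
      while (free["doc"] > 0 && !is.na(w <- pick("doc"))) {
        free["doc"] <<- free["doc"] - 1
        wait[w, "doctor"] <<- t - q_enter[w]
        start(w, "consult", svc[w, 5], t)
        progressed <- TRUE
      }
      if (!progressed) break
    }
  }

  while (any(phase != "done")) {
    active <- which(phase %in% c("pending", "service"))
    stopifnot(length(active) > 0)  # otherwise deadlock
    t <- min(until[active])
    due <- active[until[active] == t]
    for (w in sort(due)) {
      if (phase[w] == "pending") {
        join(w, "checkin_q", t)
      } else {
        complete(w, t)
      }
    }
    allocate(t)
  }

  out <- cbind(
    woman_id = seq_len(n), arrival = arrivals_at,
    checkin_wait = wait[, "checkin"], ctg_machine_wait = wait[, "machine"],
    midwife_connect_wait = wait[, "connect"],
    midwife_disconnect_wait = wait[, "disconnect"],
    doctor_wait = wait[, "doctor"], checkout_wait = wait[, "checkout"],
    departure = dep, doctor_first = as.numeric(doctor_first),
    los = dep - arrivals_at
  )
  rownames(out) <- NULL
  out
}

# FIFO pick across two queues sharing one resource (reception, midwives)
pick_first <- function(phase, queue, q_enter, qnames) {
  cand <- which(phase == "waiting" & queue %in% qnames)
  if (length(cand) == 0) return(NA_integer_)
  cand[order(q_enter[cand], cand)][1]
}

# run the package engine on the same fixed inputs and return comparable cols
engine_day <- function(arrivals_at, order_doc, n_rec, n_mid, n_doc, n_ctg,
                       svc, checks) {
  n <- length(arrivals_at)
  pattern <- if (all(arrivals_at == arrivals_at[1])) "All" else "Half"
  cfg <- clinic_config(
    arrivals = n, arrival_pattern = pattern,
    consult_order = if (order_doc) "Doc" else "Mid",
    midwives = n_mid, doctors = n_doc, ctg_machines = n_ctg,
    reception_staff = n_rec
  )
  day <- run_clinic_day(cfg, dists = NULL, service_times = svc,
                        n_checks = checks)
  r <- day$records
  out <- cbind(
    woman_id = r$woman_id, arrival = r$arrival,
    checkin_wait = r$checkin_wait, ctg_machine_wait = r$ctg_machine_wait,
    midwife_connect_wait = r$midwife_connect_wait,
    midwife_disconnect_wait = r$midwife_disconnect_wait,
    doctor_wait = r$doctor_wait, checkout_wait = r$checkout_wait,
    departure = r$departure, doctor_first = as.numeric(r$doctor_first),
    los = r$los
  )
  rownames(out) <- NULL
  out
}
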