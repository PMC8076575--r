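#include <Rcpp.h>
using namespace Rcpp;

// Single-pass cry-sequence scanner.
//
// A sequence OPENS at the first cry epoch of the earliest start_window-epoch
// sliding window containing >= start_min_cry cry epochs that lies entirely
// after the previous sequence. It CLOSES at the last cry epoch preceding the
// first run of >= stop_gap consecutive non-cry epochs (or the end of the
// series). Returns a 2-column matrix of 0-based (start, end) inclusive pairs.
// [[Rcpp::export(name = ".seq_scan_cpp")]]
IntegerMatrix seq_scan_cpp(IntegerVector labels, int start_min_cry,
                           int start_window, int stop_gap) {
  const int n = labels.size();
  std::vector<int> starts, ends;
  int from = 0; // windows must begin at or after this index

  while (from + start_window <= n) {
    // rolling count over the suffix [from, n)
    int count = 0;
    int trigger = -1;
    for (int t = from; t < n; ++t) {
      count += labels[t];
      if (t - from >= start_window) count -= labels[t - start_window];
      if (t - from >= start_window - 1 && count >= start_min_cry) {
        trigger = t; // window [t - start_window + 1, t]
        break;
      }
    }
    if (trigger < 0) break;

    int start = -1;
    for (int p = trigger - start_window + 1; p <= trigger; ++p) {
      if (labels[p] == 1) { start = p; break; }
    }

    int last_cry = start, zeros = 0, end = -1;
    for (int j = start + 1; j < n; ++j) {
      if (labels[j] == 1) {
        last_cry = j;
        zeros = 0;
      } else if (++zeros >= stop_gap) {
        break;
      }
    }
    end = last_cry;

    starts.push_back(start);
    ends.push_back(end);
    from = end + 1;
  }

  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
  }
  return out;
}

// Naive brute-force reference for the same criteria, written as direct
// quantifier checks rather than a rolling scan; kept as an internal
// validation oracle for the scanner above.
// [[Rcpp::export(name = ".seq_brute_cpp")]]
IntegerMatrix seq_brute_cpp(IntegerVector labels, int start_min_cry,
                            int start_window, int stop_gap) {
  const int n = labels.size();
  std::vector<int> starts, ends;
  int prev_end = -1;

  for (int a = 0; a + start_window <= n; ++a) {
    if (a <= prev_end) continue;
    // does the window [a, a + start_window - 1] hold enough cry epochs?
    int c = 0;
    for (int t = a; t < a + start_window; ++t) c += labels[t];
    if (c < start_min_cry) continue;
    // is this the earliest triggering window after prev_end? (by loop order, yes)
    int start = -1;
    for (int t = a; t < a + start_window; ++t) {
      if (labels[t] == 1) { start = t; break; }
    }
    // end: the furthest cry epoch reachable from start without ever crossing
    // a silence of >= stop_gap epochs between consecutive cry epochs
    int end = start;
    for (int e = start + 1; e < n; ++e) {
      if (labels[e] != 1) continue;
      // gap between end and e must stay below stop_gap for e to extend
      if (e - end - 1 < stop_gap) end = e; else break;
    }
    starts.push_back(start);
    ends.push_back(end);
    prev_end = end;
  }

  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
  }
  return out;
}
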