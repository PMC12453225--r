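#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Basal-layer lattice stepper.
//
// State is one record per site (fully occupied lattice): corrected flag,
// clone label, needle label, mutation-profile index.  Profiles are shared
// immutable sets of TP53 mutation-event ids; profile 0 is wildtype.
//
// Update scheme (both modes): each site divides independently with the
// per-step probability; dividing sites are drawn at the start of each
// step and executed in a freshly shuffled order, with whatever record
// occupies the site at its turn.  The executed division count per step
// is therefore exactly Binomial(N, q).
//
// Two execution modes:
//  * naive (optimize = false): every cell enters the Bernoulli draw.
//  * active-region (optimize = true): only cells within Manhattan
//    distance 2 of a non-background cell (corrected and/or TP53-mutant)
//    enter the draw.  Sites further out hold background cells whose
//    divisions are no-ops, except for mutation arrivals, which are
//    injected by Poisson thinning of the aggregate outside division flux
//    and executed at a uniform position in the shuffled order.  The
//    radius-2 margin keeps every first-order same-step interaction
//    partner of an expanding lineage inside the frozen order; residual
//    discrepancies are third order in the per-step division probability.
// Distributional equivalence of the two modes is a tested property.

struct Engine {
    int width, height, N;
    bool periodic;
    std::vector<int> nbr;   // 4 per site (unused tail = -1)
    std::vector<int> nnbr;

    std::vector<int> corrected, cloneId, needleId, profileId;
    std::vector<std::vector<int> > profiles; // pid-1 indexed

    // persistence by genotype class
    double pHostWT, pHostMut, pCorrWT, pCorrMut;
    double lamCorr, lamHost;

    bool optimize;
    std::vector<char> inAct;
    std::vector<int> active;

    long long corrCount, mutCount;
    int nextEventId;

    int siteOf(int x, int y) const { return x + y * width; }

    void buildNeighbors() {
        nbr.assign((size_t)N * 4, -1);
        nnbr.assign(N, 0);
        for (int y = 0; y < height; ++y) {
            for (int x = 0; x < width; ++x) {
                int s = siteOf(x, y);
                int dx[4] = { -1, 1, 0, 0 };
                int dy[4] = { 0, 0, -1, 1 };
                for (int d = 0; d < 4; ++d) {
                    int xx = x + dx[d], yy = y + dy[d];
                    if (periodic) {
                        xx = (xx + width) % width;
                        yy = (yy + height) % height;
                    } else if (xx < 0 || xx >= width || yy < 0 || yy >= height) {
                        continue;
                    }
                    nbr[(size_t)s * 4 + nnbr[s]] = siteOf(xx, yy);
                    nnbr[s]++;
                }
            }
        }
    }

    bool nonbg(int s) const { return corrected[s] != 0 || profileId[s] != 0; }

    void activate(int s) {
        if (!inAct[s]) { inAct[s] = 1; active.push_back(s); }
    }
    // activate every site within Manhattan distance 2 of s (the radius
    // needed so that all potential same-step interaction partners of an
    // expanding lineage are already in the frozen dividing draw)
    void activate2(int s) {
        int x = s % width, y = s / width;
        for (int dx = -2; dx <= 2; ++dx) {
            for (int dy = -2 + std::abs(dx); dy <= 2 - std::abs(dx); ++dy) {
                int xx = x + dx, yy = y + dy;
                if (periodic) {
                    xx = (xx % width + width) % width;
                    yy = (yy % height + height) % height;
                } else if (xx < 0 || xx >= width || yy < 0 || yy >= height) {
                    continue;
                }
                activate(siteOf(xx, yy));
            }
        }
    }

    double persis(int t) const {
        if (corrected[t]) return profileId[t] ? pCorrMut : pCorrWT;
        return profileId[t] ? pHostMut : pHostWT;
    }

    void addHits(int s, int h) {
        std::vector<int> np;
        if (profileId[s]) np = profiles[profileId[s] - 1];
        bool wasWT = np.empty();
        for (int i = 0; i < h; ++i) np.push_back(nextEventId++);
        profiles.push_back(np);
        profileId[s] = (int)profiles.size();
        if (wasWT) mutCount++;
        if (optimize) activate2(s);
    }

    // uniform site currently outside the active region
    int sampleOutside(int nOut) {
        for (int tries = 0; tries < 200; ++tries) {
            int s = (int)(unif_rand() * N);
            if (s >= N) s = N - 1;
            if (!inAct[s]) return s;
        }
        int m = (int)(unif_rand() * nOut);
        if (m >= nOut) m = nOut - 1;
        for (int s = 0; s < N; ++s)
            if (!inAct[s] && m-- == 0) return s;
        return -1; // unreachable
    }
};

// [[Rcpp::export]]
List cpp_advance(IntegerVector corrected, IntegerVector cloneId,
                 IntegerVector needleId, IntegerVector profileId,
                 List profilesIn, int width, int height, bool periodic,
                 double omega, double divProb, double dtDays,
                 double startYears, double horizonYears,
                 double snapshotIntervalYears,
                 double pHostWT, double pHostMut, double pCorrWT,
                 double pCorrMut, double lamCorr, double lamHost,
                 bool checkLoss, bool checkConfluence, double confluenceFrac,
                 bool optimize, int nextEventId) {
    Engine e;
    e.width = width; e.height = height; e.N = width * height;
    e.periodic = periodic;
    e.buildNeighbors();
    e.corrected.assign(corrected.begin(), corrected.end());
    e.cloneId.assign(cloneId.begin(), cloneId.end());
    e.needleId.assign(needleId.begin(), needleId.end());
    e.profileId.assign(profileId.begin(), profileId.end());
    e.profiles.clear();
    for (int i = 0; i < profilesIn.size(); ++i) {
        IntegerVector p = profilesIn[i];
        e.profiles.push_back(std::vector<int>(p.begin(), p.end()));
    }
    e.pHostWT = pHostWT; e.pHostMut = pHostMut;
    e.pCorrWT = pCorrWT; e.pCorrMut = pCorrMut;
    e.lamCorr = lamCorr; e.lamHost = lamHost;
    e.optimize = optimize;
    e.nextEventId = nextEventId;

    const int N = e.N;
    e.corrCount = 0; e.mutCount = 0;
    for (int s = 0; s < N; ++s) {
        if (e.corrected[s]) e.corrCount++;
        if (e.profileId[s]) e.mutCount++;
    }

    e.inAct.assign(N, 0);
    e.active.clear();
    if (optimize) {
        for (int s = 0; s < N; ++s)
            if (e.nonbg(s)) e.activate2(s);
    } else {
        for (int s = 0; s < N; ++s) e.activate(s);
    }

    int maxClone = 0, maxNeedle = 0;
    for (int s = 0; s < N; ++s) {
        if (e.cloneId[s] > maxClone) maxClone = e.cloneId[s];
        if (e.needleId[s] > maxNeedle) maxNeedle = e.needleId[s];
    }

    // snapshot buffers (plain C++ storage; converted to R objects only
    // at return, so nothing here needs GC protection)
    std::vector<double> snapTimes;
    std::vector<double> snapCorr, snapMut, snapCorrMut, snapHostMut;
    std::vector<std::vector<int> > needleSnaps, cloneSnaps, eventSnaps;

    const double daysPerYear = 365.0;
    int nSteps = (int)std::ceil(horizonYears * daysPerYear / dtDays - 1e-9);
    int snapEvery = std::max(1, (int)std::lround(snapshotIntervalYears * daysPerYear / dtDays));
    int confEvery = std::max(1, (int)std::lround(daysPerYear / dtDays / 365.0)); // once per day

    bool mutationOn = (lamCorr > 0.0 || lamHost > 0.0);

    std::vector<int> order;

    struct Snap {
        static void take(Engine &e, double tAbs, int maxClone, int maxNeedle,
                         std::vector<double> &snapTimes,
                         std::vector<double> &snapCorr, std::vector<double> &snapMut,
                         std::vector<double> &snapCorrMut, std::vector<double> &snapHostMut,
                         std::vector<std::vector<int> > &needleSnaps,
                         std::vector<std::vector<int> > &cloneSnaps,
                         std::vector<std::vector<int> > &eventSnaps) {
            int N = e.N;
            long long corrMut = 0, hostMut = 0;
            std::vector<int> nc(maxNeedle, 0), cc(maxClone, 0),
                ec(e.nextEventId - 1, 0);
            for (int s = 0; s < N; ++s) {
                bool mut = e.profileId[s] != 0;
                if (mut) {
                    if (e.corrected[s]) corrMut++; else hostMut++;
                    const std::vector<int> &pr = e.profiles[e.profileId[s] - 1];
                    for (size_t i = 0; i < pr.size(); ++i) ec[pr[i] - 1]++;
                }
                if (e.corrected[s]) {
                    if (e.needleId[s] > 0) nc[e.needleId[s] - 1]++;
                    if (e.cloneId[s] > 0) cc[e.cloneId[s] - 1]++;
                }
            }
            snapTimes.push_back(tAbs);
            snapCorr.push_back((double)e.corrCount);
            snapMut.push_back((double)e.mutCount);
            snapCorrMut.push_back((double)corrMut);
            snapHostMut.push_back((double)hostMut);
            needleSnaps.push_back(nc);
            cloneSnaps.push_back(cc);
            eventSnaps.push_back(ec);
        }
    };

    int outcome = 0; // 0 ongoing, 1 loss, 2 confluence
    double eventTime = NA_REAL;
    double confCells = confluenceFrac * N - 1e-9;

    Snap::take(e, startYears, maxClone, maxNeedle, snapTimes, snapCorr, snapMut,
               snapCorrMut, snapHostMut, needleSnaps, cloneSnaps, eventSnaps);

    // endpoint can already hold at entry (e.g. whole-grid delivery)
    if (checkLoss && e.corrCount == 0) { outcome = 1; eventTime = startYears; }
    if (outcome == 0 && checkConfluence && (double)e.corrCount >= confCells) {
        outcome = 2; eventTime = startYears;
    }

    int step = 0;
    std::vector<int> arrivalStamp(N, -1);
    if (outcome == 0) {
        for (step = 1; step <= nSteps; ++step) {
            double tNow = startYears + step * dtDays / daysPerYear;

            // mutation arrivals from divisions outside the active region:
            // the arriving cell's division is a basal no-op (all its
            // neighbours are background), so only the hit itself and its
            // same-step exposure to neighbouring divisions need modelling
            order.clear();
            if (optimize && mutationOn && lamHost > 0.0) {
                int nOut = N - (int)e.active.size();
                if (nOut > 0) {
                    double nDiv = R::rbinom((double)nOut, divProb);
                    int H = (int)R::rpois(nDiv * lamHost);
                    for (int h = 0; h < H; ++h) {
                        int s = e.sampleOutside(N - (int)e.active.size());
                        if (s < 0) continue;
                        order.push_back(s + N);   // forced division + hit
                        arrivalStamp[s] = step;
                        e.activate2(s);
                    }
                }
            }

            // freeze the dividing set: Bernoulli draw over active cells
            int na = (int)e.active.size();
            for (int i = 0; i < na; ++i) {
                int s = e.active[i];
                if (arrivalStamp[s] == step) continue;  // already forced
                if (unif_rand() < divProb) order.push_back(s);
            }
            for (int i = (int)order.size() - 1; i > 0; --i) {
                int j = (int)(unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(order[i], order[j]);
            }

            for (size_t oi = 0; oi < order.size(); ++oi) {
                int s = order[oi];
                bool forcedHit = s >= N;
                if (forcedHit) s -= N;
                bool vertical = true;
                int tgt = -1;
                if (unif_rand() >= omega) {
                    int j = (int)(unif_rand() * e.nnbr[s]);
                    if (j >= e.nnbr[s]) j = e.nnbr[s] - 1;
                    tgt = e.nbr[(size_t)s * 4 + j];
                    double p = e.persis(tgt);
                    if (p <= 0.0 || unif_rand() >= p) vertical = false;
                }
                if (!vertical) {
                    // displaced record leaves the basal layer; parent copy
                    // takes the site
                    if (e.corrected[tgt] != e.corrected[s])
                        e.corrCount += e.corrected[s] ? 1 : -1;
                    bool tgtMut = e.profileId[tgt] != 0;
                    bool srcMut = e.profileId[s] != 0;
                    if (tgtMut != srcMut) e.mutCount += srcMut ? 1 : -1;
                    e.corrected[tgt] = e.corrected[s];
                    e.cloneId[tgt] = e.cloneId[s];
                    e.needleId[tgt] = e.needleId[s];
                    e.profileId[tgt] = e.profileId[s];
                    if (optimize && e.nonbg(tgt)) e.activate2(tgt);
                }
                // mutation for the daughter retained at the parent site
                if (forcedHit) {
                    e.addHits(s, 1);
                } else if (mutationOn) {
                    double lam = e.corrected[s] ? lamCorr : lamHost;
                    if (lam > 0.0) {
                        int h = (int)R::rpois(lam);
                        if (h > 0) e.addHits(s, h);
                    }
                }
            }

            // endpoints: loss every step, confluence once per simulated day
            if (checkLoss && e.corrCount == 0) {
                outcome = 1; eventTime = tNow;
            } else if (checkConfluence && step % confEvery == 0 &&
                       (double)e.corrCount >= confCells) {
                outcome = 2; eventTime = tNow;
            }

            if (step % snapEvery == 0 || outcome != 0 || step == nSteps) {
                Snap::take(e, tNow, maxClone, maxNeedle, snapTimes, snapCorr,
                           snapMut, snapCorrMut, snapHostMut, needleSnaps,
                           cloneSnaps, eventSnaps);
            }
            if (outcome != 0) break;
            if (step % 2000 == 0) Rcpp::checkUserInterrupt();
        }
    }

    List profOut(e.profiles.size());
    for (size_t i = 0; i < e.profiles.size(); ++i)
        profOut[i] = IntegerVector(e.profiles[i].begin(), e.profiles[i].end());

    List needleL(needleSnaps.size()), cloneL(cloneSnaps.size()), eventL(eventSnaps.size());
    for (size_t i = 0; i < needleSnaps.size(); ++i)
        needleL[i] = IntegerVector(needleSnaps[i].begin(), needleSnaps[i].end());
    for (size_t i = 0; i < cloneSnaps.size(); ++i)
        cloneL[i] = IntegerVector(cloneSnaps[i].begin(), cloneSnaps[i].end());
    for (size_t i = 0; i < eventSnaps.size(); ++i)
        eventL[i] = IntegerVector(eventSnaps[i].begin(), eventSnaps[i].end());

    return List::create(
        _["corrected"] = IntegerVector(e.corrected.begin(), e.corrected.end()),
        _["cloneId"] = IntegerVector(e.cloneId.begin(), e.cloneId.end()),
        _["needleId"] = IntegerVector(e.needleId.begin(), e.needleId.end()),
        _["profileId"] = IntegerVector(e.profileId.begin(), e.profileId.end()),
        _["profiles"] = profOut,
        _["nextEventId"] = e.nextEventId,
        _["outcome"] = outcome,
        _["eventTime"] = eventTime,
        _["snapTimes"] = NumericVector(snapTimes.begin(), snapTimes.end()),
        _["snapCorrected"] = NumericVector(snapCorr.begin(), snapCorr.end()),
        _["snapTP53"] = NumericVector(snapMut.begin(), snapMut.end()),
        _["snapCorrMut"] = NumericVector(snapCorrMut.begin(), snapCorrMut.end()),
        _["snapHostMut"] = NumericVector(snapHostMut.begin(), snapHostMut.end()),
        _["snapNeedleCounts"] = needleL,
        _["snapCloneCounts"] = cloneL,
        _["snapEventCounts"] = eventL);
}
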