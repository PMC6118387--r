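# Packaged model parameterization. The system block is identical across
# both packaged drugs; per-segment values inside printed ranges are the
# package defaults and are user-overridable.
drug:
  name: clonazepam
  MW: 315.7
  logP: 2.41
  pKa:
    - {value: 1.86, type: base}
    - {value: 11.89, type: acid}
  pgpSubstrate: true
  affinityPgp: 0.1
  releaseProbPgp: 1.0
  cypSubstrate: true
  affinityCyp: 0.2
  releaseProbCyp: 1.0
  metabolizeProbCyp: 0.02
  binderSubstrate: true
  affinityBinder: 1.0
  releaseProbBinder: 0.05
experiment:
  Steps: 10000
  TimeScale: 0.01
  numSolutes: 500
  MeasureScale: 0.948
  clinicalDose: 2
  samplingTimes: [0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 48, 72, 96]
  replicates: 14
  smoothN: 10
  route: stomach
system:
  systemSize: [20, 20, 20]
  spaces:
    stomach:              {spacepH: 2.5, flowRate: 0.70}
    duodenum:             {spacepH: 6.0, flowRate: 0.02}
    jejunum:              {spacepH: 6.0, flowRate: 0.03}
    ileum:                {spacepH: 6.0, flowRate: 0.04}
    colon_egested:        {spacepH: 6.0, flowRate: 0.0}
    enterocytes_duodenum: {spacepH: 7.4, flowRate: 0.0}
    enterocytes_jejunum:  {spacepH: 7.4, flowRate: 0.0}
    enterocytes_ileum:    {spacepH: 7.4, flowRate: 0.0}
    portal_vein:          {spacepH: 7.4, flowRate: 5.0}
    sinusoid:             {spacepH: 7.4, flowRate: 5.0}
    hepatocyte:           {spacepH: 7.4, flowRate: 0.0}
    systemic_blood:       {spacepH: 7.4, flowRate: 5.0}
    other_organs:         {spacepH: 7.4, flowRate: 0.0}
  flows:
    - {from: stomach, to: duodenum,             flowDepthFrac: 0.5,  flowFrac: 0.9}
    - {from: duodenum, to: jejunum,             flowDepthFrac: 0.1,  flowFrac: 0.15}
    - {from: jejunum, to: ileum,                flowDepthFrac: 0.1,  flowFrac: 0.15}
    - {from: ileum, to: colon_egested,          flowDepthFrac: 0.2,  flowFrac: 0.2}
    - {from: portal_vein, to: sinusoid,         flowDepthFrac: 1.0,  flowFrac: 0.8}
    - {from: sinusoid, to: systemic_blood,      flowDepthFrac: 0.5,  flowFrac: 0.3}
    - {from: systemic_blood, to: other_organs,  flowDepthFrac: 1.0,  flowFrac: 0.5}
    - {from: systemic_blood, to: portal_vein,   flowDepthFrac: 1.0,  flowFrac: 1.0}
    - {from: other_organs, to: systemic_blood,  flowDepthFrac: 1.0,  flowFrac: 1.0}
  membranes:
    - {from: enterocytes_duodenum, to: portal_vein, poresFrac: 0.0,
       interfaceDepthFrac: 0.8, leakinessFrac: 0.8, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: enterocytes_jejunum, to: portal_vein, poresFrac: 0.0,
       interfaceDepthFrac: 0.8, leakinessFrac: 0.8, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: enterocytes_ileum, to: portal_vein, poresFrac: 0.0,
       interfaceDepthFrac: 0.8, leakinessFrac: 0.8, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: duodenum, to: enterocytes_duodenum, poresFrac: 0.02,
       interfaceDepthFrac: 0.6, leakinessFrac: 0.6, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: jejunum, to: enterocytes_jejunum, poresFrac: 0.02,
       interfaceDepthFrac: 0.7, leakinessFrac: 0.7, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: ileum, to: enterocytes_ileum, poresFrac: 0.02,
       interfaceDepthFrac: 0.8, leakinessFrac: 0.8, uptakeProb: 0.0, uptakeFrac: 0.0}
    - {from: sinusoid, to: hepatocyte, poresFrac: 0.0,
       interfaceDepthFrac: 0.1, leakinessFrac: 0.1, uptakeProb: 0.2, uptakeFrac: 0.2}
  sites:
    - {kind: cyp, space: enterocytes_duodenum, count: 1, maxActiveSites: 1, Neighborhood: 9}
    - {kind: cyp, space: enterocytes_jejunum,  count: 2, maxActiveSites: 1, Neighborhood: 9}
    - {kind: cyp, space: enterocytes_ileum,    count: 2, maxActiveSites: 1, Neighborhood: 9}
    - {kind: cyp, space: hepatocyte,           count: 60, maxActiveSites: 1, Neighborhood: 9}
    - {kind: pgp, space: enterocytes_duodenum, count: 1, maxActiveSites: 1, Neighborhood: 9}
    - {kind: pgp, space: enterocytes_jejunum,  count: 5, maxActiveSites: 1, Neighborhood: 9}
    - {kind: pgp, space: enterocytes_ileum,    count: 5, maxActiveSites: 1, Neighborhood: 9}
    - {kind: binder, space: systemic_blood,    count: 200, maxActiveSites: 3, Neighborhood: 3}
    - {kind: binder, space: other_organs,      count: 500, maxActiveSites: 1, Neighborhood: 1}

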