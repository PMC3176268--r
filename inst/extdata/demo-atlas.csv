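#regions
CA1,field CA1,demo
ENT,entorhinal area,demo
ENTadj1,synthetic neighbor region 1 adjacent to ENT,demo
ENTadj2,synthetic neighbor region 2 adjacent to ENT,demo
ENTadj3,synthetic neighbor region 3 adjacent to ENT,demo
ENTl,entorhinal area lateral part,demo
ENTm,entorhinal area medial part,demo
POST,postsubiculum,demo
RSP,retrosplenial area,demo
RSPd,retrosplenial area dorsal part,demo
RSPv,retrosplenial area ventral part,demo
RSPv-a,retrosplenial area ventral part zone a,demo
RSPv-b/c,retrosplenial area ventral part zones b/c,demo
#part_of
ENTl,ENT
ENTm,ENT
RSPd,RSP
RSPv,RSP
RSPv-a,RSPv
RSPv-b/c,RSPv
#overlaps
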