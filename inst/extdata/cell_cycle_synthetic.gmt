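S_synthetic	synthetic S-phase program	chr7_g030	chr7_g033	chr7_g036	chr7_g039	chr7_g042	chr7_g045	chr7_g048	chr7_g051	chr7_g054	chr7_g057
G2M_synthetic	synthetic G2M program	chr19_g030	chr19_g033	chr19_g036	chr19_g039	chr19_g042	chr19_g045	chr19_g048	chr19_g051	chr19_g054	chr19_g057
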