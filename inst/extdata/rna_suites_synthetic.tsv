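suite	delta_m1	epsilon_m1	zeta_m1	alpha	beta	gamma	delta
1a	98	-153	-71	-68	178	54	98
s02	98	-153	-71	-65	174	-170	98
s03	98	-153	-71	-65	174	-65	98
s04	98	-153	-71	-65	80	54	98
s05	98	-153	-71	-65	80	-170	98
s06	98	-153	-71	-65	80	-65	98
s07	98	-153	-71	65	174	54	98
s08	98	-153	-71	65	174	-170	98
s09	98	-153	-71	65	174	-65	98
s10	98	-153	-71	65	80	54	98
s11	98	-153	-71	65	80	-170	98
s12	98	-153	-71	65	80	-65	98
s13	98	-153	-71	165	174	54	98
s14	98	-153	-71	165	174	-170	98
s15	98	-153	-71	165	174	-65	98
s16	98	-153	-71	165	80	54	98
s17	98	-153	-71	165	80	-170	98
s18	98	-153	-71	165	80	-65	98
s19	98	-153	60	-65	174	54	98
s20	98	-153	60	-65	174	-170	98
s21	98	-153	60	-65	174	-65	98
s22	98	-153	60	-65	80	54	98
s23	98	-153	60	-65	80	-170	98
s24	98	-153	60	-65	80	-65	98
s25	98	-153	60	65	174	54	98
s26	98	-153	60	65	174	-170	98
s27	98	-153	60	65	174	-65	98
s28	98	-153	60	65	80	54	98
s29	98	-153	60	65	80	-170	98
s30	98	-153	60	65	80	-65	98
s31	98	-153	60	165	174	54	98
s32	98	-153	60	165	174	-170	98
s33	98	-153	60	165	174	-65	98
s34	98	-153	60	165	80	54	98
s35	98	-153	60	165	80	-170	98
s36	98	-153	60	165	80	-65	98
s37	98	-153	170	-65	174	54	98
s38	98	-153	170	-65	174	-170	98
s39	98	-153	170	-65	174	-65	98
s40	98	-153	170	-65	80	54	98
s41	98	-153	170	-65	80	-170	98
s42	98	-153	170	-65	80	-65	98
s43	98	-153	170	65	174	54	98
s44	98	-153	170	65	174	-170	98
s45	98	-153	170	65	174	-65	98
s46	98	-153	170	65	80	54	98
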