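id	cell01	cell02	cell03	cell04	cell05	cell06	cell07	cell08	cell09	cell10	cell11	cell12	cell13	cell14	cell15	cell16	cell17	cell18
cell01	1	0.946021	0.93689900000000004	0.92155900000000002	0.97175400000000001	0.93222000000000005	-0.38656600000000002	-0.252523	-0.26583800000000002	-0.381301	-0.31430799999999998	-0.32091199999999998	0.124502	0.13022800000000001	0.135711	0.113958	0.087079000000000004	0.11297699999999999
cell02	0.946021	1	0.93981499999999996	0.92116399999999998	0.91602300000000003	0.96033800000000002	-0.36754900000000001	-0.20158899999999999	-0.250467	-0.36588100000000001	-0.31795800000000002	-0.28114099999999997	0.19825100000000001	0.181315	0.184695	0.18606900000000001	0.15594	0.16431799999999999
cell03	0.93689900000000004	0.93981499999999996	1	0.95116900000000004	0.94225700000000001	0.93420199999999998	-0.37731300000000001	-0.14600399999999999	-0.22265499999999999	-0.330125	-0.28890300000000002	-0.27921200000000002	0.014205000000000001	-0.0022070000000000002	0.028715000000000001	0.013559999999999999	-0.041078999999999997	-0.018128999999999999
cell04	0.92155900000000002	0.92116399999999998	0.95116900000000004	1	0.92385600000000001	0.93340599999999996	-0.26364799999999999	-0.073591000000000004	-0.10950699999999999	-0.23613100000000001	-0.185194	-0.16094600000000001	0.15119099999999999	0.13229099999999999	0.17128699999999999	0.16497100000000001	0.110606	0.12786
cell05	0.97175400000000001	0.91602300000000003	0.94225700000000001	0.92385600000000001	1	0.90976000000000001	-0.39927400000000002	-0.202266	-0.24745800000000001	-0.36495499999999997	-0.31398700000000002	-0.30038100000000001	0.14132400000000001	0.14478199999999999	0.14820700000000001	0.13658100000000001	0.102297	0.12199599999999999
cell06	0.93222000000000005	0.96033800000000002	0.93420199999999998	0.93340599999999996	0.90976000000000001	1	-0.337368	-0.18098600000000001	-0.22592999999999999	-0.34734599999999999	-0.29087299999999999	-0.24704100000000001	0.26900099999999999	0.25480199999999997	0.28290599999999999	0.25756000000000001	0.21929799999999999	0.222138
cell07	-0.38656600000000002	-0.36754900000000001	-0.37731300000000001	-0.26364799999999999	-0.39927400000000002	-0.337368	1	0.87038700000000002	0.95881300000000003	0.94012899999999999	0.895486	0.93503499999999995	0.18192	0.214255	0.29470099999999999	0.14266699999999999	0.175819	0.13651199999999999
cell08	-0.252523	-0.20158899999999999	-0.14600399999999999	-0.073591000000000004	-0.202266	-0.18098600000000001	0.87038700000000002	1	0.92954800000000004	0.944326	0.89870300000000003	0.92422400000000005	0.103229	0.11294899999999999	0.20866999999999999	0.050634999999999999	0.078090999999999994	-0.0048679999999999999
cell09	-0.26583800000000002	-0.250467	-0.22265499999999999	-0.10950699999999999	-0.24745800000000001	-0.22592999999999999	0.95881300000000003	0.92954800000000004	1	0.94257899999999994	0.92093000000000003	0.95908300000000002	0.18097099999999999	0.21190800000000001	0.30574800000000002	0.14022200000000001	0.180063	0.123484
cell10	-0.381301	-0.36588100000000001	-0.330125	-0.23613100000000001	-0.36495499999999997	-0.34734599999999999	0.94012899999999999	0.944326	0.94257899999999994	1	0.93904699999999997	0.94398899999999997	0.123075	0.10997700000000001	0.20897499999999999	0.080085000000000003	0.099047999999999997	0.031118
cell11	-0.31430799999999998	-0.31795800000000002	-0.28890300000000002	-0.185194	-0.31398700000000002	-0.29087299999999999	0.895486	0.89870300000000003	0.92093000000000003	0.93904699999999997	1	0.93945900000000004	0.148313	0.17060700000000001	0.25507800000000003	0.12124600000000001	0.14335200000000001	0.074866000000000002
cell12	-0.32091199999999998	-0.28114099999999997	-0.27921200000000002	-0.16094600000000001	-0.30038100000000001	-0.24704100000000001	0.93503499999999995	0.92422400000000005	0.95908300000000002	0.94398899999999997	0.93945900000000004	1	0.27309499999999998	0.26744699999999999	0.361848	0.22579399999999999	0.248639	0.15601100000000001
cell13	0.124502	0.19825100000000001	0.014205000000000001	0.15119099999999999	0.14132400000000001	0.26900099999999999	0.18192	0.103229	0.18097099999999999	0.123075	0.148313	0.27309499999999998	1	0.95462999999999998	0.94730700000000001	0.97577999999999998	0.97165199999999996	0.94093000000000004
cell14	0.13022800000000001	0.181315	-0.0022070000000000002	0.13229099999999999	0.14478199999999999	0.25480199999999997	0.214255	0.11294899999999999	0.21190800000000001	0.10997700000000001	0.17060700000000001	0.26744699999999999	0.95462999999999998	1	0.95315000000000005	0.94333999999999996	0.97402299999999997	0.95108899999999996
cell15	0.135711	0.184695	0.028715000000000001	0.17128699999999999	0.14820700000000001	0.28290599999999999	0.29470099999999999	0.20866999999999999	0.30574800000000002	0.20897499999999999	0.25507800000000003	0.361848	0.94730700000000001	0.95315000000000005	1	0.94143399999999999	0.95269899999999996	0.91208999999999996
cell16	0.113958	0.18606900000000001	0.013559999999999999	0.16497100000000001	0.13658100000000001	0.25756000000000001	0.14266699999999999	0.050634999999999999	0.14022200000000001	0.080085000000000003	0.12124600000000001	0.22579399999999999	0.97577999999999998	0.94333999999999996	0.94143399999999999	1	0.97678799999999999	0.94936900000000002
cell17	0.087079000000000004	0.15594	-0.041078999999999997	0.110606	0.102297	0.21929799999999999	0.175819	0.078090999999999994	0.180063	0.099047999999999997	0.14335200000000001	0.248639	0.97165199999999996	0.97402299999999997	0.95269899999999996	0.97678799999999999	1	0.95580799999999999
cell18	0.11297699999999999	0.16431799999999999	-0.018128999999999999	0.12786	0.12199599999999999	0.222138	0.13651199999999999	-0.0048679999999999999	0.123484	0.031118	0.074866000000000002	0.15601100000000001	0.94093000000000004	0.95108899999999996	0.91208999999999996	0.94936900000000002	0.95580799999999999	1
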